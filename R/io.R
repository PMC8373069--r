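# CSV / JSON round-trip for every pipeline table. All files carry explicit
# headers; numeric columns are in the units stated in the docs (s, um, nm^3,
# nM). Readers skip malformed rows and report the skip count via the
# "n_skipped" attribute.

#' Write and read trajectory tables
#'
#' The on-disk dialect is one row per frame:
#' `particle_id,channel,frame,time_s,position_um,censored`.
#'
#' @param trajs list of [trajectory()] objects.
#' @param path CSV file path.
#' @return `write_trajectories_csv` returns `path` invisibly;
#'   `read_trajectories_csv` returns a list of trajectories (attribute
#'   `n_skipped` counts malformed rows dropped).
#' @export
write_trajectories_csv <- function(trajs, path) {
  rows <- lapply(trajs, function(tr) {
    data.frame(particle_id = tr$particle_id, channel = tr$channel,
               frame = seq_along(tr$times) - 1L,
               time_s = tr$times, position_um = tr$positions,
               censored = tr$censored, stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(particle_id = character(), channel = character(),
               frame = integer(), time_s = numeric(),
               position_um = numeric(), censored = logical())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @export
read_trajectories_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$time_s <- suppressWarnings(as.numeric(df$time_s))
  df$position_um <- suppressWarnings(as.numeric(df$position_um))
  ok <- is.finite(df$time_s) & is.finite(df$position_um) &
    !is.na(df$particle_id)
  n_skipped <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  trajs <- lapply(split(df, paste(df$particle_id, df$channel)), function(d) {
    d <- d[order(d$time_s), , drop = FALSE]
    if (nrow(d) < 2L) return(NULL)
    trajectory(d$particle_id[1L], d$time_s, d$position_um,
               channel = as.character(d$channel[1L]),
               censored = isTRUE(as.logical(d$censored[1L])))
  })
  trajs <- unname(Filter(Negate(is.null), trajs))
  attr(trajs, "n_skipped") <- n_skipped
  trajs
}

#' Write and read dwell-record tables (`particle_id,duration_s,observed`)
#'
#' @param records a [dwell_records()] data frame.
#' @param path CSV file path.
#' @export
write_dwell_csv <- function(records, path) {
  utils::write.csv(
    data.frame(particle_id = records$particle_id,
               duration_s = records$duration,
               observed = records$observed),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dwell_csv
#' @export
read_dwell_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$duration_s <- suppressWarnings(as.numeric(df$duration_s))
  obs <- suppressWarnings(as.logical(df$observed))
  ok <- is.finite(df$duration_s) & df$duration_s > 0 & !is.na(obs)
  df$observed <- obs
  n_skipped <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  out <- dwell_records(df$duration_s, as.logical(df$observed),
                       particle_id = df$particle_id)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write per-particle diffusion estimates
#' (`particle_id,D_um2_per_s,alpha,r2,fraction_used,valid,motility`)
#'
#' @param df data frame with those columns (see [run_report()]).
#' @param path CSV file path.
#' @export
write_estimates_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
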