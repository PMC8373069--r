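#' Single-particle trajectory on a DNA tightrope
#'
#' Container for a time-ordered 1-D position series recorded at a uniform
#' frame interval.
#'
#' @param particle_id identifier (coerced to character).
#' @param times acquisition times, s; must be strictly increasing and
#'   uniformly spaced (to within 1e-9 s).
#' @param positions positions along the tightrope, um; finite, same length
#'   as `times`, length >= 2.
#' @param channel emission-channel label (e.g. `"605"`, `"705"`).
#' @param censored `TRUE` when the particle persisted past the end of the
#'   observation window (its bound lifetime is right-censored).
#' @return an object of class `trajectory`.
#' @examples
#' tr <- trajectory("p1", times = (0:9) / 12.5, positions = rnorm(10, sd = 0.03))
#' tr
#' @export
trajectory <- function(particle_id, times, positions,
                       channel = "605", censored = FALSE) {
  if (length(times) < 2L)
    stop("a trajectory needs at least 2 frames, got ", length(times))
  if (length(times) != length(positions))
    stop_bad_arg("positions", "must match times in length")
  check_numeric_vec(positions, "positions")
  check_numeric_vec(times, "times")
  dts <- diff(times)
  if (any(dts <= 0)) stop_bad_arg("times", "must be strictly increasing")
  if (diff(range(dts)) > 1e-9)
    stop_bad_arg("times", "must lie on a uniform frame grid (1e-9 s tolerance)")
  structure(
    list(particle_id = as.character(particle_id)[1L],
         channel = as.character(channel)[1L],
         times = as.numeric(times), positions = as.numeric(positions),
         censored = isTRUE(censored), dt = mean(dts)),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory %s (channel %s): %d frames, dt = %.4g s%s\n",
              x$particle_id, x$channel, length(x$times), x$dt,
              if (x$censored) ", censored" else ""))
  invisible(x)
}

#' Mean squared displacement of a trajectory
#'
#' Time-averaged MSD with overlapping windows:
#' \deqn{MSD(n\Delta t) = \frac{1}{N-n}\sum_{i=1}^{N-n}(x_{i+n}-x_i)^2}
#' for lag `n = 1, ..., floor(max_lag_fraction * (N - 1))`.
#'
#' @param traj a [trajectory()].
#' @param max_lag_fraction largest lag to evaluate, as a fraction of the
#'   maximal lag `N - 1` (default 1 = the full curve).
#' @return a data frame of class `msd_profile` with columns `lag`
#'   (frames), `lag_time` (s), `msd` (um^2), `n_pairs`; attribute
#'   `n_lags_full` records `N - 1` so downstream fits can express their fit
#'   range as a fraction of the whole MSD plot.
#' @examples
#' tr <- trajectory("p1", (0:99) * 0.08, cumsum(rnorm(100, sd = 0.02)))
#' head(compute_msd(tr))
#' @export
compute_msd <- function(traj, max_lag_fraction = 1) {
  stopifnot(inherits(traj, "trajectory"))
  check_number(max_lag_fraction, "max_lag_fraction", lower = 1e-12, upper = 1)
  x <- traj$positions
  N <- length(x)
  n_max <- max(1L, as.integer(floor(max_lag_fraction * (N - 1L))))
  msd <- vapply(seq_len(n_max), function(n) {
    d <- x[(1L + n):N] - x[seq_len(N - n)]
    sum(d * d) / (N - n)
  }, numeric(1))
  out <- data.frame(lag = seq_len(n_max),
                    lag_time = seq_len(n_max) * traj$dt,
                    msd = msd,
                    n_pairs = N - seq_len(n_max))
  attr(out, "n_lags_full") <- N - 1L
  attr(out, "particle_id") <- traj$particle_id
  class(out) <- c("msd_profile", "data.frame")
  out
}

new_diffusion_fit <- function(D, y_intercept, alpha, r_squared,
                              fraction_used, valid, method, n_points) {
  structure(
    list(D = D, y_intercept = y_intercept, alpha = alpha,
         r_squared = r_squared, fraction_of_plot_used = fraction_used,
         valid = valid, method = method, n_points = n_points),
    class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("Diffusion fit (%s): D = %.4g um^2/s, alpha = %s\n",
              x$method, x$D,
              if (is.na(x$alpha)) "-" else sprintf("%.3f", x$alpha)))
  cat(sprintf("  R^2 = %.3f over %.0f%% of the MSD plot (%d lags); %s\n",
              x$r_squared, 100 * x$fraction_of_plot_used, x$n_points,
              if (isTRUE(x$valid)) "valid" else "rejected by filter"))
  invisible(x)
}

#' @export
coef.diffusion_fit <- function(object, ...) {
  c(D = object$D, y_intercept = object$y_intercept, alpha = object$alpha)
}

fit_range <- function(profile, fit_fraction) {
  stopifnot(inherits(profile, "msd_profile"))
  check_number(fit_fraction, "fit_fraction", lower = 1e-12, upper = 1)
  n_fit <- max(1L, as.integer(floor(fit_fraction * nrow(profile))))
  profile[seq_len(n_fit), , drop = FALSE]
}

plot_fraction <- function(profile, n_used) {
  n_full <- attr(profile, "n_lags_full") %||% nrow(profile)
  n_used / n_full
}

#' Diffusion coefficient from a linear MSD fit
#'
#' Ordinary least squares of `MSD(n dt) = 2 D (n dt) + y` over the first
#' `fit_fraction` of lags; the intercept `y` absorbs static localization
#' error. Fits with `R^2` below `r2_threshold` or using less than
#' `min_plot_fraction` of the full MSD plot are marked invalid rather than
#' removed.
#'
#' @param profile an [compute_msd()] profile.
#' @param fit_fraction fraction of the profile's lags used for the fit
#'   (default 0.25).
#' @param r2_threshold validity threshold on `R^2` (default 0.8).
#' @param min_plot_fraction minimum fraction of the full MSD plot the fit
#'   must use to be considered (default 0.10).
#' @return a `diffusion_fit` with `D` (um^2/s), `y_intercept` (um^2),
#'   `r_squared`, `fraction_of_plot_used` and the `valid` flag. Fewer than 3
#'   usable lag points yields an invalid fit, never an error.
#' @export
fit_msd_linear <- function(profile, fit_fraction = 0.25,
                           r2_threshold = 0.8, min_plot_fraction = 0.10) {
  sub <- fit_range(profile, fit_fraction)
  frac_used <- plot_fraction(profile, nrow(sub))
  if (nrow(sub) < 3L)
    return(new_diffusion_fit(NA_real_, NA_real_, NA_real_, NA_real_,
                             frac_used, FALSE, "linear", nrow(sub)))
  fit <- stats::lm(msd ~ lag_time, data = sub)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  slope <- unname(stats::coef(fit)[2L])
  valid <- is.finite(r2) && r2 >= r2_threshold &&
    frac_used >= min_plot_fraction
  new_diffusion_fit(D = slope / 2,
                    y_intercept = unname(stats::coef(fit)[1L]),
                    alpha = NA_real_, r_squared = r2,
                    fraction_used = frac_used, valid = valid,
                    method = "linear", n_points = nrow(sub))
}

#' Anomalous diffusion exponent from a log-log MSD fit
#'
#' Least-squares regression of `log(MSD)` on `log(lag time)` over the first
#' `fit_fraction` of lags: the slope is the anomalous exponent `alpha`
#' (`MSD ~ t^alpha`) and the intercept gives `D` through
#' `MSD = 2 D t^alpha`. Non-positive MSD values are dropped from the fit
#' range; the same validity filter as [fit_msd_linear()] applies.
#'
#' @inheritParams fit_msd_linear
#' @return a `diffusion_fit` with `alpha`, `D`, `r_squared`,
#'   `fraction_of_plot_used`, `valid`.
#' @export
fit_alpha <- function(profile, fit_fraction = 0.25,
                      r2_threshold = 0.8, min_plot_fraction = 0.10) {
  sub <- fit_range(profile, fit_fraction)
  sub <- sub[sub$msd > 0, , drop = FALSE]
  frac_used <- plot_fraction(profile, nrow(sub))
  if (nrow(sub) < 3L)
    return(new_diffusion_fit(NA_real_, NA_real_, NA_real_, NA_real_,
                             frac_used, FALSE, "loglog", nrow(sub)))
  fit <- stats::lm(log(msd) ~ log(lag_time), data = sub)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  alpha <- unname(stats::coef(fit)[2L])
  valid <- is.finite(r2) && r2 >= r2_threshold &&
    frac_used >= min_plot_fraction
  new_diffusion_fit(D = exp(unname(stats::coef(fit)[1L])) / 2,
                    y_intercept = 0, alpha = alpha, r_squared = r2,
                    fraction_used = frac_used, valid = valid,
                    method = "loglog", n_points = nrow(sub))
}

# rolling standard deviation over trailing windows of w frames, O(n);
# value at index i summarizes frames [i - w + 1, i] (edges use the first
# full window's value)
rolling_sd <- function(x, w) {
  n <- length(x)
  if (n < w) return(rep(stats::sd(x), n))
  s1 <- cumsum(x)
  s2 <- cumsum(x * x)
  i <- w:n
  sum1 <- s1[i] - c(0, s1)[i - w + 1L]
  sum2 <- s2[i] - c(0, s2)[i - w + 1L]
  v <- pmax((sum2 - sum1^2 / w) / (w - 1L), 0)
  out <- numeric(n)
  out[i] <- sqrt(v)
  out[seq_len(w - 1L)] <- out[w]
  out
}

#' Segment a trajectory into motile and stationary phases
#'
#' Rolling standard deviation of position over `window_frames` compared to
#' `motile_threshold`; contiguous equal-label frames are merged into phases
#' and phases shorter than `min_phase_frames` are absorbed into their longer
#' neighbour. A trajectory shorter than the rolling window becomes a single
#' phase labelled by its whole-track SD.
#'
#' @param traj a [trajectory()].
#' @param window_frames rolling-window length in frames (>= 3; default 10).
#' @param motile_threshold positional SD above which a window is called
#'   motile, um (default 0.09, i.e. 3x the typical 0.03 um localization
#'   noise).
#' @param min_phase_frames shortest phase retained (default
#'   `window_frames`).
#' @return data frame of class `phase_segments`: `particle_id`,
#'   `start_frame`, `end_frame` (1-based, inclusive), `label`
#'   (`"motile"`/`"stationary"`).
#' @export
segment_phases <- function(traj, window_frames = 10, motile_threshold = 0.09,
                           min_phase_frames = window_frames) {
  stopifnot(inherits(traj, "trajectory"))
  check_number(window_frames, "window_frames", lower = 3)
  check_number(motile_threshold, "motile_threshold", lower = 0)
  n <- length(traj$positions)
  sds <- rolling_sd(traj$positions, as.integer(window_frames))
  lab <- ifelse(sds > motile_threshold, "motile", "stationary")
  r <- rle(lab)
  # absorb sub-minimal runs into their larger neighbour, shortest first
  while (length(r$lengths) > 1L && min(r$lengths) < min_phase_frames) {
    j <- which.min(r$lengths)
    nb <- if (j == 1L) 2L
          else if (j == length(r$lengths)) j - 1L
          else if (r$lengths[j - 1L] >= r$lengths[j + 1L]) j - 1L else j + 1L
    r$lengths[nb] <- r$lengths[nb] + r$lengths[j]
    r$lengths <- r$lengths[-j]
    r$values <- r$values[-j]
    merged <- rle(rep(r$values, r$lengths))   # re-merge equal neighbours
    r <- merged
  }
  ends <- cumsum(r$lengths)
  out <- data.frame(particle_id = traj$particle_id,
                    start_frame = c(1L, utils::head(ends, -1L) + 1L),
                    end_frame = ends,
                    label = r$values,
                    stringsAsFactors = FALSE)
  class(out) <- c("phase_segments", "data.frame")
  out
}

#' Classify particles as motile or stationary
#'
#' A particle is motile iff it has at least one motile phase.
#'
#' @param segments a `phase_segments` data frame (one or several particles,
#'   e.g. `rbind` of per-trajectory segmentations).
#' @return data frame with `particle_id` and `motility`
#'   (`"motile"`/`"stationary"`), one row per particle.
#' @export
classify_motility <- function(segments) {
  stopifnot(is.data.frame(segments), nrow(segments) > 0L)
  ids <- unique(segments$particle_id)
  mot <- vapply(ids, function(id) {
    any(segments$label[segments$particle_id == id] == "motile")
  }, logical(1))
  data.frame(particle_id = ids,
             motility = ifelse(mot, "motile", "stationary"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Motile fraction of a trajectory cohort
#'
#' Segments every trajectory, classifies each particle, and returns the
#' cohort motile fraction with a binomial standard error.
#'
#' @param trajs list of [trajectory()] objects.
#' @param ... passed to [segment_phases()].
#' @return list with `fraction`, `se`, `n_motile`, `n_total`, `calls`.
#' @export
motility_summary <- function(trajs, ...) {
  stopifnot(length(trajs) > 0L)
  segs <- do.call(rbind, lapply(trajs, segment_phases, ...))
  calls <- classify_motility(segs)
  p <- mean(calls$motility == "motile")
  n <- nrow(calls)
  list(fraction = p, se = sqrt(p * (1 - p) / n),
       n_motile = sum(calls$motility == "motile"), n_total = n,
       calls = calls)
}

#' Two-colour colocalization by concurrent proximity
#'
#' A cross-channel pair colocalizes when the two particles are within
#' `distance_threshold` of each other for at least `min_overlap_frames`
#' concurrent frames. Qualifying pairs are matched one-to-one greedily by
#' ascending mean separation (ties broken by lower particle id). The
#' reported fraction follows the Venn convention: colocalized particles
#' divided by the union of particles in both channels.
#'
#' @param trajs_a,trajs_b lists of [trajectory()] objects from the two
#'   channels (channel labels must differ).
#' @param distance_threshold colocalization radius, um (default 0.2).
#' @param min_overlap_frames minimum number of concurrent within-threshold
#'   frames (default 10).
#' @return object of class `coloc_result`: `n_channel_a`, `n_channel_b`,
#'   `n_colocalized`, `fraction_colocalized`, `pairs` (data frame of matched
#'   ids), `empty_channel` flag.
#' @export
colocalization_fraction <- function(trajs_a, trajs_b,
                                    distance_threshold = 0.2,
                                    min_overlap_frames = 10) {
  check_number(distance_threshold, "distance_threshold", lower = 0)
  check_number(min_overlap_frames, "min_overlap_frames", lower = 1)
  na <- length(trajs_a); nb <- length(trajs_b)
  if (na > 0L && nb > 0L) {
    ch_a <- unique(vapply(trajs_a, `[[`, "", "channel"))
    ch_b <- unique(vapply(trajs_b, `[[`, "", "channel"))
    if (length(intersect(ch_a, ch_b)) > 0L)
      stop("the two channels must carry distinct labels")
  }
  if (na == 0L || nb == 0L) {
    warning("one channel is empty; colocalization fraction is 0")
    return(structure(list(n_channel_a = na, n_channel_b = nb,
                          n_colocalized = 0L, fraction_colocalized = 0,
                          pairs = data.frame(), empty_channel = TRUE),
                     class = "coloc_result"))
  }
  cand <- list(); ci <- 0L
  for (i in seq_len(na)) {
    ta <- trajs_a[[i]]
    for (j in seq_len(nb)) {
      tb <- trajs_b[[j]]
      k <- min(length(ta$times), length(tb$times))
      if (k < min_overlap_frames) next
      if (abs(ta$times[1L] - tb$times[1L]) > 1e-9 ||
          abs(ta$dt - tb$dt) > 1e-9) next
      d <- abs(ta$positions[seq_len(k)] - tb$positions[seq_len(k)])
      if (sum(d <= distance_threshold) >= min_overlap_frames) {
        ci <- ci + 1L
        cand[[ci]] <- data.frame(i = i, j = j,
                                 id_a = ta$particle_id, id_b = tb$particle_id,
                                 mean_dist = mean(d),
                                 stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- data.frame()
  if (ci > 0L) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$mean_dist, cand$id_a, cand$id_b), , drop = FALSE]
    used_a <- logical(na); used_b <- logical(nb); keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      if (!used_a[cand$i[r]] && !used_b[cand$j[r]]) {
        keep[r] <- TRUE
        used_a[cand$i[r]] <- TRUE
        used_b[cand$j[r]] <- TRUE
      }
    }
    pairs <- cand[keep, c("id_a", "id_b", "mean_dist"), drop = FALSE]
    row.names(pairs) <- NULL
  }
  n_co <- nrow(pairs)
  structure(list(n_channel_a = na, n_channel_b = nb, n_colocalized = n_co,
                 fraction_colocalized = n_co / (na + nb - n_co),
                 pairs = pairs, empty_channel = FALSE),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(paste0("Colocalization: %d of %d particles ",
                     "(%d + %d - %d overlap) = %.1f%%\n"),
              x$n_colocalized, x$n_channel_a + x$n_channel_b - x$n_colocalized,
              x$n_channel_a, x$n_channel_b, x$n_colocalized,
              100 * x$fraction_colocalized))
  invisible(x)
}
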