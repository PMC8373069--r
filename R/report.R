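#' Emit a complete synthetic fixture directory
#'
#' Generates every input the analysis stages consume -- a two-channel
#' trajectory table, dwell records, an AFM field with its calibration
#' table, a pair of excision time courses and a binding isotherm -- together
#' with the ground truth and the resolved configuration as JSON sidecars.
#' Deterministic under the configuration seed.
#'
#' @param config a [sim_config()]; its `seed` drives every draw.
#' @param dir output directory (created if needed).
#' @param afm_species,afm_weights molecular-weight means (kDa) and mixing
#'   weights of the simulated AFM species. Defaults place four separated
#'   populations standing in for a glycosylase monomer and dimer, a damage
#'   sensor, and their co-complex.
#' @param afm_n,afm_noise_sd AFM field size and volume noise (nm^3).
#' @param kd,titrant isotherm ground truth (nM) and titration series.
#' @param excision burst-model ground truth: list with `amplitude`,
#'   `k_burst`, `kss_minus`, `kss_plus`, `substrate`, `times`, `noise_sd`.
#' @return the directory path, invisibly.
#' @export
run_simulate <- function(config, dir,
                         afm_species = c(60, 120, 175, 235),
                         afm_weights = c(0.35, 0.15, 0.35, 0.15),
                         afm_n = 400, afm_noise_sd = 12,
                         kd = 4, titrant = c(0, 1, 2, 4, 8, 16, 32, 64),
                         excision = list(amplitude = 8, k_burst = 0.01,
                                         kss_minus = 2e-5, kss_plus = 1e-4,
                                         substrate = 50,
                                         times = c(0, 30, 60, 120, 300, 600,
                                                   1800, 3600, 7200, 14400),
                                         noise_sd = 1)) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seed <- config$seed %||% 1L

  sim <- simulate_tightrope_particles(config, two_channel = TRUE)
  write_trajectories_csv(sim$trajectories, file.path(dir, "trajectories.csv"))
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE)

  dw <- simulate_dwell_times(max(config$n_particles, 1L),
                             half_life = config$half_life_true,
                             window = config$window, seed = seed + 1L)
  write_dwell_csv(dw, file.path(dir, "dwell.csv"))

  cal <- data.frame(label = c("calA", "calB", "calC"),
                    mw_kda = c(50, 110, 220),
                    volume_nm3 = c(78, 162, 335))  # synthetic calibration
  utils::write.csv(cal, file.path(dir, "calibration.csv"), row.names = FALSE)
  curve <- fit_standard_curve(cal)
  afm <- simulate_afm_field(afm_species, afm_weights, curve,
                            n = afm_n, noise_sd = afm_noise_sd,
                            seed = seed + 2L)
  utils::write.csv(afm, file.path(dir, "afm.csv"), row.names = FALSE)

  tc_minus <- simulate_excision_timecourse(
    excision$amplitude, excision$k_burst, excision$kss_minus,
    excision$substrate, excision$times, excision$noise_sd, seed = seed + 3L)
  tc_plus <- simulate_excision_timecourse(
    excision$amplitude, excision$k_burst, excision$kss_plus,
    excision$substrate, excision$times, excision$noise_sd, seed = seed + 4L)
  utils::write.csv(as.data.frame(tc_minus),
                   file.path(dir, "excision_minus.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(tc_plus),
                   file.path(dir, "excision_plus.csv"), row.names = FALSE)

  iso <- simulate_binding_isotherm(kd, dna_total = 8, titrant = titrant,
                                   noise_sd = 0.02, seed = seed + 5L)
  utils::write.csv(as.data.frame(iso), file.path(dir, "isotherm.csv"),
                   row.names = FALSE)

  resolved <- c(unclass(config),
                list(afm_species = afm_species, afm_weights = afm_weights,
                     afm_n = afm_n, afm_noise_sd = afm_noise_sd,
                     kd = kd, titrant = titrant, dna_total = 8,
                     excision = excision,
                     substrate_total = excision$substrate))
  jsonlite::write_json(resolved, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' End-to-end analysis report over a fixture directory
#'
#' Runs every analysis stage on the tables written by [run_simulate()] (or
#' equivalently formatted real extractions) and collects the headline
#' quantities: motile fraction, valid diffusion-coefficient and
#' anomalous-exponent distributions, half-life estimates by both methods,
#' dissociation frequency, two-colour colocalization, the AFM species
#' table, the fitted dissociation constant and the fold-stimulation of
#' excision. Re-running on the same directory reproduces the same JSON.
#'
#' @param dir fixture directory.
#' @param fit_fraction MSD fit range (fraction of lags, default 0.25).
#' @param motile_threshold,window_frames phase-segmentation parameters.
#' @param distance_threshold,min_overlap_frames colocalization parameters.
#' @param afm_k number of AFM mixture components (default 4).
#' @param write write `report.json` and `estimates.csv` into `dir`
#'   (default `TRUE`).
#' @return the report as a named list (also serialized to
#'   `report.json`), including `n_rows_skipped`, the count of malformed
#'   input rows dropped across tables.
#' @export
run_report <- function(dir, fit_fraction = 0.25, motile_threshold = 0.09,
                       window_frames = 10, distance_threshold = 0.2,
                       min_overlap_frames = 10, afm_k = 4, write = TRUE) {
  need <- c("trajectories.csv", "dwell.csv", "afm.csv", "calibration.csv",
            "excision_minus.csv", "excision_plus.csv", "isotherm.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0L)
    stop("fixture directory is missing: ", paste(missing, collapse = ", "))
  skipped <- 0L

  trajs <- read_trajectories_csv(file.path(dir, "trajectories.csv"))
  skipped <- skipped + (attr(trajs, "n_skipped") %||% 0L)
  channels <- vapply(trajs, `[[`, "", "channel")
  chan_levels <- sort(unique(channels))

  est <- lapply(trajs, function(tr) {
    prof <- compute_msd(tr)
    lin <- fit_msd_linear(prof, fit_fraction)
    al <- fit_alpha(prof, fit_fraction)
    segs <- segment_phases(tr, window_frames, motile_threshold)
    data.frame(particle_id = tr$particle_id, channel = tr$channel,
               D_um2_per_s = lin$D, alpha = al$alpha,
               r2 = lin$r_squared, fraction_used = lin$fraction_of_plot_used,
               valid = lin$valid,
               motility = classify_motility(segs)$motility,
               stringsAsFactors = FALSE)
  })
  est <- do.call(rbind, est)
  motile <- est$motility == "motile"
  # D and alpha are summarized over motile particles with valid fits, as in
  # practice; if none qualify, fall back to all valid fits
  valid_mot <- est$valid & motile
  if (!any(valid_mot)) valid_mot <- est$valid

  dw <- read_dwell_csv(file.path(dir, "dwell.csv"))
  skipped <- skipped + (attr(dw, "n_skipped") %||% 0L)
  hl_ls <- tryCatch(fit_half_life(dw, "least_squares"), error = function(e) NULL)
  hl_mle <- tryCatch(fit_half_life(dw, "mle_censored"), error = function(e) NULL)
  dfreq <- dissociation_frequency(dw)

  coloc <- if (length(chan_levels) >= 2L) {
    colocalization_fraction(trajs[channels == chan_levels[1L]],
                            trajs[channels == chan_levels[2L]],
                            distance_threshold, min_overlap_frames)
  } else NULL

  cal <- utils::read.csv(file.path(dir, "calibration.csv"))
  curve <- fit_standard_curve(cal)
  afm <- utils::read.csv(file.path(dir, "afm.csv"))
  ok <- is.finite(afm$v_complex_nm3) & is.finite(afm$v_dna1_nm3) &
    is.finite(afm$v_dna2_nm3)
  skipped <- skipped + sum(!ok)
  afm <- afm[ok, , drop = FALSE]
  v_prot <- protein_volume_from_complex(afm$v_complex_nm3, afm$v_dna1_nm3,
                                        afm$v_dna2_nm3)
  mws <- mw_from_volume(curve, v_prot)
  mix <- fit_species_gaussians(mws, k = afm_k, seed = 1L)

  tc_minus <- read_timecourse_csv(file.path(dir, "excision_minus.csv"))
  tc_plus <- read_timecourse_csv(file.path(dir, "excision_plus.csv"))
  fold <- stimulation_fold(tc_minus, tc_plus)

  iso <- utils::read.csv(file.path(dir, "isotherm.csv"))
  cfg_path <- file.path(dir, "config.json")
  dna_total <- if (file.exists(cfg_path))
    jsonlite::read_json(cfg_path)$dna_total %||% 8 else 8
  kdfit <- fit_quadratic_kd(iso, dna_total = dna_total)

  report <- list(
    n_particles = nrow(est),
    motile_fraction = mean(motile),
    mean_D_um2_per_s = mean(est$D_um2_per_s[valid_mot]),
    mean_alpha = mean(est$alpha[valid_mot], na.rm = TRUE),
    n_valid_fits = sum(est$valid),
    half_life_ls_s = if (is.null(hl_ls)) NA else hl_ls$half_life,
    half_life_mle_s = if (is.null(hl_mle)) NA else hl_mle$half_life,
    dissociation_frequency = dfreq$frequency,
    colocalized_fraction = if (is.null(coloc)) NA else
      coloc$fraction_colocalized,
    afm_species = mix$components,
    afm_bic = mix$bic,
    kd_nM = kdfit$kd,
    stimulation_fold_product = fold$fold_product,
    stimulation_fold_kss = fold$fold_kss,
    n_rows_skipped = skipped)
  if (write) {
    write_estimates_csv(est, file.path(dir, "estimates.csv"))
    jsonlite::write_json(report, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  report
}

read_timecourse_csv <- function(path) {
  df <- utils::read.csv(path)
  excision_timecourse(df$time_s, df$product_percent,
                      substrate_total = max(df$product_nM * 100 /
                                              pmax(df$product_percent, 1e-9),
                                            na.rm = TRUE))
}
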