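#' Simulation configuration for the tightrope observables
#'
#' Bundles and validates every parameter of the single-molecule generator.
#' Defaults correspond to the glycosylase-alone imaging condition: 12.5
#' frames/s over a 300 s observation window, 10% motile particles, mean
#' diffusion coefficient 3.75e-3 um^2/s, anomalous exponent 1.19, bound-state
#' half-life 8900 s (hence heavy right-censoring at 300 s), abasic sites
#' every 2 kb along the tightrope, and 0.03 um localization noise typical of
#' quantum-dot tracking.
#'
#' @param frame_rate imaging rate, frames/s (> 0).
#' @param window observation window, s (> 0).
#' @param n_particles number of particles to simulate (>= 0).
#' @param motile_fraction probability a particle is motile, in \[0, 1\].
#' @param D_true generalized diffusion coefficient of motile particles,
#'   um^2/s (>= 0); the ensemble MSD is `2 * D_true * t^alpha_true`.
#' @param alpha_true anomalous diffusion exponent in (0, 2); 1 is ordinary
#'   Brownian motion, > 1 superdiffusive, < 1 subdiffusive.
#' @param loc_noise_sd localization noise s.d., um (>= 0).
#' @param half_life_true bound-state half-life, s (> 0); lifetimes are
#'   exponential with mean `half_life_true / log(2)`.
#' @param coloc_fraction fraction of all particles that are co-bound pairs
#'   in two-channel mode, in \[0, 1\].
#' @param site_spacing spacing of damage sites along the DNA, kb (> 0).
#' @param bp_to_um contour-length conversion, um/kb (0.34 for B-DNA).
#' @param seed optional integer seed; identical seeds give bit-identical
#'   output.
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_particles = 5, seed = 1)
#' cfg$half_life_true
#' @export
sim_config <- function(frame_rate = 12.5,
                       window = 300,
                       n_particles = 100,
                       motile_fraction = 0.10,
                       D_true = 3.75e-3,
                       alpha_true = 1.19,
                       loc_noise_sd = 0.03,
                       half_life_true = 8900,
                       coloc_fraction = 0.24,
                       site_spacing = 2,
                       bp_to_um = 0.34,
                       seed = NULL) {
  check_number(frame_rate, "frame_rate", lower = 1e-9)
  check_number(window, "window", lower = 1e-9)
  check_number(n_particles, "n_particles", lower = 0)
  if (n_particles != round(n_particles))
    stop_bad_arg("n_particles", "must be a whole number")
  check_number(motile_fraction, "motile_fraction", lower = 0, upper = 1)
  check_number(D_true, "D_true", lower = 0)
  check_number(alpha_true, "alpha_true")
  if (alpha_true <= 0 || alpha_true >= 2)
    stop_bad_arg("alpha_true", "must lie strictly inside (0, 2)")
  check_number(loc_noise_sd, "loc_noise_sd", lower = 0)
  check_number(half_life_true, "half_life_true", lower = 1e-12)
  check_number(coloc_fraction, "coloc_fraction", lower = 0, upper = 1)
  check_number(site_spacing, "site_spacing", lower = 1e-12)
  check_number(bp_to_um, "bp_to_um", lower = 1e-12)
  if (!is.null(seed)) {
    check_number(seed, "seed")
    if (seed != round(seed)) stop_bad_arg("seed", "must be an integer")
  }
  structure(
    list(frame_rate = frame_rate, window = window,
         n_particles = as.integer(n_particles),
         motile_fraction = motile_fraction, D_true = D_true,
         alpha_true = alpha_true, loc_noise_sd = loc_noise_sd,
         half_life_true = half_life_true, coloc_fraction = coloc_fraction,
         site_spacing = site_spacing, bp_to_um = bp_to_um,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Tightrope simulation configuration\n")
  cat(sprintf("  %g fps over %g s window; %d particles\n",
              x$frame_rate, x$window, x$n_particles))
  cat(sprintf("  motile fraction %.2f; D = %.3g um^2/s; alpha = %.3g\n",
              x$motile_fraction, x$D_true, x$alpha_true))
  cat(sprintf("  half-life %g s; coloc fraction %.2f; loc noise %.3g um\n",
              x$half_life_true, x$coloc_fraction, x$loc_noise_sd))
  cat(sprintf("  sites every %g kb (%g um/kb); seed %s\n",
              x$site_spacing, x$bp_to_um,
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}
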