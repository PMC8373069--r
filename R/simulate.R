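#' Simulate quantum-dot labelled particles on a DNA tightrope
#'
#' Generates per-frame 1-D positions for a cohort of particles bound to a
#' damage-site array, with known ground truth. Each particle draws an
#' exponential bound lifetime (mean `half_life_true / log(2)`), truncated at
#' the observation window and flagged censored when it survives past it.
#' Motile particles follow fractional Brownian motion with Hurst exponent
#' `alpha_true / 2` scaled so the ensemble MSD is `2 * D_true * t^alpha_true`
#' (a plain Gaussian random walk when `alpha_true = 1`); stationary particles
#' sit at a fixed site. Independent Gaussian localization noise is added to
#' every frame. Particles are placed on consecutive damage sites
#' (`site_spacing * bp_to_um` um apart).
#'
#' In two-channel mode a fraction `coloc_fraction` of particles are co-bound
#' pairs: the partner appears in the second channel, shares the underlying
#' path (the pair moves together), and carries its own localization noise.
#' The remaining singletons are split between the channels at random.
#'
#' @param config a [sim_config()].
#' @param two_channel simulate a dual-colour field (default `FALSE`).
#' @param channels labels for the one or two channels.
#' @return a list with elements
#'   * `trajectories`: list of [trajectory()] objects;
#'   * `truth`: data frame with one row per simulated particle
#'     (`particle_id`, `channel`, `is_motile`, `is_cobound`,
#'     `true_lifetime`, `censored`, `site_um`).
#' @examples
#' sim <- simulate_tightrope_particles(sim_config(n_particles = 3, seed = 7))
#' sim$truth
#' @export
simulate_tightrope_particles <- function(config,
                                         two_channel = FALSE,
                                         channels = c("605", "705")) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_particles
  dt <- 1 / config$frame_rate
  site_step <- config$site_spacing * config$bp_to_um
  if (n == 0L) {
    return(list(trajectories = list(), truth = empty_truth()))
  }

  ids <- sprintf("p%04d", seq_len(n))
  lifetimes <- stats::rexp(n, rate = log(2) / config$half_life_true)
  motile <- stats::runif(n) < config$motile_fraction
  if (two_channel) {
    n_pair <- round(config$coloc_fraction * n)
    cobound <- seq_len(n) <= n_pair       # deterministic count, as configured
    single_chan <- sample(channels, n, replace = TRUE)
    chan <- ifelse(cobound, channels[1L], single_chan)
  } else {
    cobound <- rep(FALSE, n)
    chan <- rep(channels[1L], n)
  }

  trajs <- vector("list", n + sum(cobound))
  truth <- data.frame(
    particle_id = ids, channel = chan, is_motile = motile,
    is_cobound = cobound, true_lifetime = lifetimes,
    censored = lifetimes >= config$window,
    site_um = (seq_len(n) - 1L) * site_step,
    stringsAsFactors = FALSE)

  slot <- 1L
  for (i in seq_len(n)) {
    dur <- min(lifetimes[i], config$window)
    n_frames <- max(2L, as.integer(floor(dur / dt)) + 1L)
    times <- (seq_len(n_frames) - 1L) * dt
    path <- if (motile[i]) {
      truth$site_um[i] +
        sqrt(2 * config$D_true) * sample_displacement(
          n_frames - 1L, config$alpha_true, dt)
    } else {
      rep(truth$site_um[i], n_frames)
    }
    pos <- path + stats::rnorm(n_frames, sd = config$loc_noise_sd)
    trajs[[slot]] <- trajectory(ids[i], times, pos, channel = chan[i],
                                censored = truth$censored[i])
    slot <- slot + 1L
    if (cobound[i]) {
      pos_b <- path + stats::rnorm(n_frames, sd = config$loc_noise_sd)
      trajs[[slot]] <- trajectory(paste0(ids[i], "b"), times, pos_b,
                                  channel = channels[2L],
                                  censored = truth$censored[i])
      slot <- slot + 1L
    }
  }
  list(trajectories = trajs, truth = truth)
}

# displacement path of length n+1 (starting at 0) with MSD(t) = t^alpha
# after the sqrt(2D) scaling applied by the caller
sample_displacement <- function(n, alpha, dt) {
  if (abs(alpha - 1) < 1e-12) {
    c(0, cumsum(stats::rnorm(n, sd = sqrt(dt))))
  } else {
    fbm_path(n, alpha / 2, dt)
  }
}

empty_truth <- function() {
  data.frame(particle_id = character(), channel = character(),
             is_motile = logical(), is_cobound = logical(),
             true_lifetime = numeric(), censored = logical(),
             site_um = numeric(), stringsAsFactors = FALSE)
}

#' Simulate bound-state dwell times with right-censoring
#'
#' Draws exponential lifetimes at a given half-life and censors them at the
#' observation window, mirroring what a finite single-molecule movie records.
#'
#' @param n number of particles.
#' @param half_life ground-truth half-life, s; the exponential mean is
#'   `half_life / log(2)`.
#' @param window observation window, s; `Inf` (default) disables censoring.
#' @param seed optional integer seed.
#' @return a `dwell_records` data frame (`particle_id`, `duration`,
#'   `observed`).
#' @examples
#' d <- simulate_dwell_times(5, half_life = 590, window = 300, seed = 1)
#' table(d$observed)
#' @export
simulate_dwell_times <- function(n, half_life, window = Inf, seed = NULL) {
  check_number(n, "n", lower = 1)
  check_number(half_life, "half_life", lower = 1e-12)
  if (!identical(window, Inf)) check_number(window, "window", lower = 1e-12)
  if (!is.null(seed)) set.seed(seed)
  life <- stats::rexp(n, rate = log(2) / half_life)
  observed <- life < window
  dwell_records(duration = pmin(life, window), observed = observed,
                particle_id = sprintf("p%04d", seq_len(n)))
}

#' Simulate an AFM field of protein and protein-DNA species
#'
#' Draws particle species by weight, converts molecular weight to expected
#' AFM volume through a volume-vs-MW standard curve, adds Gaussian volume
#' noise, and attaches flanking-DNA volumes so that the DNA-subtraction
#' formula recovers the protein volume. Ground-truth species labels are
#' retained.
#'
#' @param species_means molecular weights of the species, kDa.
#' @param species_weights mixing weights (must sum to 1).
#' @param curve an [fit_standard_curve()] object (or a list with `slope`,
#'   `intercept`).
#' @param n number of particles.
#' @param noise_sd s.d. of the protein-volume noise, nm^3.
#' @param seed optional integer seed.
#' @param dna_volume_mean,dna_volume_sd distribution of the flanking-DNA
#'   volumes, nm^3.
#' @return data frame of class `afm_field`: `particle_id`, `species` (truth
#'   label), `mw_true_kda`, `v_complex_nm3`, `v_dna1_nm3`, `v_dna2_nm3`.
#' @export
simulate_afm_field <- function(species_means, species_weights, curve, n,
                               noise_sd, seed = NULL,
                               dna_volume_mean = 30, dna_volume_sd = 4) {
  check_numeric_vec(species_means, "species_means", lower = 0)
  check_numeric_vec(species_weights, "species_weights", lower = 0)
  if (length(species_means) != length(species_weights))
    stop_bad_arg("species_weights", "must match species_means in length")
  if (abs(sum(species_weights) - 1) > 1e-9)
    stop_bad_arg("species_weights", "must sum to 1")
  check_number(n, "n", lower = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  slope <- curve$slope
  intercept <- curve$intercept
  check_number(slope, "curve$slope", lower = 1e-12)
  check_number(intercept, "curve$intercept")
  if (!is.null(seed)) set.seed(seed)

  lab <- sample.int(length(species_means), n, replace = TRUE,
                    prob = species_weights)
  mw <- species_means[lab]
  v_prot <- intercept + slope * mw + stats::rnorm(n, sd = noise_sd)
  v_dna1 <- pmax(stats::rnorm(n, dna_volume_mean, dna_volume_sd), 0)
  v_dna2 <- pmax(stats::rnorm(n, dna_volume_mean, dna_volume_sd), 0)
  out <- data.frame(
    particle_id = sprintf("a%04d", seq_len(n)),
    species = lab, mw_true_kda = mw,
    v_complex_nm3 = v_prot + (v_dna1 + v_dna2) / 2,
    v_dna1_nm3 = v_dna1, v_dna2_nm3 = v_dna2,
    stringsAsFactors = FALSE)
  class(out) <- c("afm_field", "data.frame")
  out
}

#' Simulate a glycosylase excision time course
#'
#' Product follows the pre-steady-state burst form
#' `A0 * (1 - exp(-k_burst * t)) + A0 * k_ss * t`, clamped at the available
#' substrate, with optional Gaussian noise on the percent scale.
#'
#' @param amplitude burst amplitude `A0` (active enzyme), nM.
#' @param k_burst burst rate constant, 1/s.
#' @param k_ss steady-state turnover rate per enzyme, 1/s.
#' @param substrate_cap total substrate, nM; product can never exceed it.
#' @param times sampling times, s (ascending).
#' @param noise_sd Gaussian noise s.d. in percent-of-substrate units.
#' @param seed optional integer seed.
#' @return an [excision_timecourse()] with `time_s`, `product_nM`,
#'   `product_percent`. If `amplitude > substrate_cap` the course is still
#'   produced but carries attribute `burst_exceeds_substrate = TRUE`.
#' @export
simulate_excision_timecourse <- function(amplitude, k_burst, k_ss,
                                         substrate_cap, times,
                                         noise_sd = 0, seed = NULL) {
  check_number(amplitude, "amplitude", lower = 0)
  check_number(k_burst, "k_burst", lower = 0)
  check_number(k_ss, "k_ss", lower = 0)
  check_number(substrate_cap, "substrate_cap", lower = 1e-12)
  check_numeric_vec(times, "times", lower = 0)
  if (is.unsorted(times)) stop_bad_arg("times", "must be ascending")
  check_number(noise_sd, "noise_sd", lower = 0)
  if (!is.null(seed)) set.seed(seed)

  model_nM <- pmin(substrate_cap,
                   amplitude * (1 - exp(-k_burst * times)) +
                     amplitude * k_ss * times)
  pct <- 100 * model_nM / substrate_cap +
    stats::rnorm(length(times), sd = noise_sd)
  tc <- excision_timecourse(times, product_percent = pct,
                            substrate_total = substrate_cap)
  if (amplitude > substrate_cap) {
    warning("burst amplitude exceeds total substrate; course is clamped")
    attr(tc, "burst_exceeds_substrate") <- TRUE
  }
  tc
}

#' Simulate an equilibrium binding isotherm (EMSA-style)
#'
#' Fraction of DNA bound from the exact single-site ligand-depletion
#' (quadratic) solution at each titrant concentration, plus Gaussian noise,
#' clipped to \[0, 1\].
#'
#' @param kd dissociation constant, nM (> 0).
#' @param dna_total total DNA, nM (> 0).
#' @param titrant protein concentrations, nM (>= 0).
#' @param noise_sd Gaussian noise s.d. on the fraction-bound scale.
#' @param seed optional integer seed.
#' @return a `binding_isotherm` data frame (`titrant_nM`, `fraction_bound`)
#'   with attribute `dna_total`.
#' @export
simulate_binding_isotherm <- function(kd, dna_total, titrant,
                                      noise_sd = 0, seed = NULL) {
  check_number(kd, "kd", lower = 1e-12)
  check_number(dna_total, "dna_total", lower = 1e-12)
  check_numeric_vec(titrant, "titrant", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (!is.null(seed)) set.seed(seed)
  f <- fraction_bound_quadratic(titrant, dna_total, kd) +
    stats::rnorm(length(titrant), sd = noise_sd)
  out <- data.frame(titrant_nM = titrant,
                    fraction_bound = pmin(pmax(f, 0), 1))
  attr(out, "dna_total") <- dna_total
  class(out) <- c("binding_isotherm", "data.frame")
  out
}
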