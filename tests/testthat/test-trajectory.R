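test_that("MSD matches closed forms and the hand-computed case", {
  # constant positions: identically zero
  expect_equal(compute_msd(make_traj(rep(2, 10)))$msd, rep(0, 9))
  # ballistic drift at v = 1 um/s: MSD(n) = (v n dt)^2
  expect_equal(compute_msd(make_traj(0:5))$msd, c(1, 4, 9, 16, 25))
  # hand-worked example
  p <- compute_msd(make_traj(c(0, 1, 0, 2, 1)))
  expect_equal(p$msd, c(1.75, 2 / 3, 2, 1))
  expect_equal(p$n_pairs, c(4, 3, 2, 1))
})

test_that("MSD equals the double-loop oracle exactly", {
  set.seed(8)
  for (rep in 1:20) {
    N <- sample(5:200, 1)
    x <- as.numeric(sample(-50:50, N, replace = TRUE))  # integers in float
    expect_identical(compute_msd(make_traj(x))$msd, msd_oracle(x))
  }
})

test_that("MSD is invariant to position offset and time reversal", {
  set.seed(9)
  x <- cumsum(rnorm(80))
  base <- compute_msd(make_traj(x))$msd
  expect_equal(compute_msd(make_traj(x + 13.7))$msd, base)
  expect_equal(compute_msd(make_traj(rev(x)))$msd, base)
})

test_that("linear MSD fit recovers an exact line and applies the filter", {
  lag_t <- (1:40) * 0.08
  prof <- structure(
    data.frame(lag = 1:40, lag_time = lag_t, msd = 0.2 * lag_t + 0.01,
               n_pairs = 160 - (1:40)),
    n_lags_full = 160L, class = c("msd_profile", "data.frame"))
  fit <- fit_msd_linear(prof, fit_fraction = 1)
  expect_equal(fit$D, 0.1, tolerance = 1e-12)
  expect_equal(fit$y_intercept, 0.01, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_true(fit$valid)
  # under 3 points: invalid, never an error
  short <- fit_msd_linear(prof[1:2, ], fit_fraction = 1)
  expect_false(short$valid)
  expect_true(is.na(short$D))
  # fits using < 10% of the plot are rejected
  narrow <- fit_msd_linear(prof, fit_fraction = 0.25)  # 10/160 lags
  expect_false(narrow$valid)
  expect_equal(narrow$fraction_of_plot_used, 10 / 160)
})

test_that("noisy profiles with low R2 are flagged invalid", {
  set.seed(4)
  lag_t <- (1:50) * 0.08
  prof <- structure(
    data.frame(lag = 1:50, lag_time = lag_t,
               msd = abs(0.01 * lag_t + rnorm(50, sd = 0.05)),
               n_pairs = 51 - (1:50)),
    n_lags_full = 50L, class = c("msd_profile", "data.frame"))
  fit <- fit_msd_linear(prof, fit_fraction = 1)
  expect_lt(fit$r_squared, 0.8)
  expect_false(fit$valid)
  # lowering the R2 threshold never invalidates a previously valid fit
  for (thr in c(0.8, 0.5, 0.2)) {
    f_hi <- fit_msd_linear(prof, 1, r2_threshold = thr)
    f_lo <- fit_msd_linear(prof, 1, r2_threshold = thr / 2)
    expect_true(!f_hi$valid || f_lo$valid)
  }
})

test_that("log-log fit hits the Brownian and ballistic limits exactly", {
  lag_t <- (1:60) * 0.08
  mk <- function(msd) structure(
    data.frame(lag = seq_along(msd), lag_time = lag_t, msd = msd,
               n_pairs = 61 - seq_along(msd)),
    n_lags_full = 60L, class = c("msd_profile", "data.frame"))
  brown <- fit_alpha(mk(2 * 0.05 * lag_t), fit_fraction = 1)
  expect_equal(brown$alpha, 1, tolerance = 1e-10)
  ball <- fit_alpha(mk(0.3 * lag_t^2), fit_fraction = 1)
  expect_equal(ball$alpha, 2, tolerance = 1e-10)
  # on exact Brownian MSD both routes agree on D to 1e-12 relative
  lin <- fit_msd_linear(mk(2 * 0.05 * lag_t), fit_fraction = 1)
  expect_equal(brown$D, lin$D, tolerance = 1e-12)
  expect_equal(brown$D, 0.05, tolerance = 1e-12)
})

test_that("per-particle D and alpha are recovered across exponents", {
  dt <- 1 / 12.5
  for (a in c(0.8, 1.0, 1.2)) {
    set.seed(99)
    est <- t(replicate(200, {
      tr <- make_motile_track(1500, D = 3.75e-3, alpha = a, dt = dt)
      f <- fit_alpha(compute_msd(tr))
      c(f$alpha, f$D)
    }))
    expect_lt(abs(mean(est[, 1]) - a), 0.08)
    expect_lt(abs(stats::median(est[, 2]) - 3.75e-3) / 3.75e-3, 0.10)
  }
})

test_that("phase segmentation separates noise from motion", {
  set.seed(21)
  # pure localization noise: one stationary phase
  tr <- make_traj(rnorm(300, sd = 0.03), dt = 1 / 12.5)
  segs <- segment_phases(tr)
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$label, "stationary")
  # sustained Brownian motion: called motile
  tr2 <- make_motile_track(300, D = 1e-2, alpha = 1, noise_sd = 0.03)
  expect_identical(classify_motility(segment_phases(tr2))$motility, "motile")
  # constructed stationary | motile | stationary track: 3 phases with
  # boundaries within one rolling window of the construction
  set.seed(22)
  w <- 10
  x <- c(rnorm(150, sd = 0.02),
         0.25 * cumsum(rnorm(150)) + rnorm(150, sd = 0.02))
  x <- c(x, x[300] + rnorm(150, sd = 0.02))
  segs3 <- segment_phases(make_traj(x, dt = 0.08), window_frames = w,
                          motile_threshold = 0.09)
  expect_identical(segs3$label, c("stationary", "motile", "stationary"))
  expect_lt(abs(segs3$start_frame[2] - 151), w + 1)
  expect_lt(abs(segs3$end_frame[2] - 300), w + 1)
})

test_that("motility classification aggregates phases per particle", {
  segs <- data.frame(particle_id = c("a", "a", "b"),
                     start_frame = c(1, 51, 1), end_frame = c(50, 100, 100),
                     label = c("stationary", "motile", "stationary"))
  calls <- classify_motility(segs)
  expect_identical(calls$motility[calls$particle_id == "a"], "motile")
  expect_identical(calls$motility[calls$particle_id == "b"], "stationary")
})

test_that("motile fraction is recovered on a mixed cohort", {
  cfg <- sim_config(n_particles = 100, motile_fraction = 0.10, D_true = 1e-2,
                    alpha_true = 1.0, half_life_true = 1e9, window = 80,
                    seed = 31)
  sim <- simulate_tightrope_particles(cfg)
  ms <- motility_summary(sim$trajectories)
  # the classifier recovers the realized motile proportion of this cohort
  # (short 80 s tracks: a few slow-moving motile particles may be missed)
  expect_lt(abs(ms$fraction - mean(sim$truth$is_motile)), 0.05)
  # and agrees with the generator labels particle by particle
  m <- merge(ms$calls, sim$truth[, c("particle_id", "is_motile")])
  expect_gt(mean((m$motility == "motile") == m$is_motile), 0.95)
})

test_that("colocalization handles the exact and impossible limits", {
  set.seed(41)
  xs <- lapply(1:5, function(i) rnorm(60, mean = i, sd = 0.02))
  a <- lapply(1:5, function(i) make_traj(xs[[i]], dt = 0.08,
                                         id = sprintf("a%d", i)))
  b <- lapply(1:5, function(i) make_traj(xs[[i]], dt = 0.08,
                                         id = sprintf("b%d", i),
                                         channel = "705"))
  res <- colocalization_fraction(a, b)
  expect_identical(res$n_colocalized, 5L)
  expect_equal(res$fraction_colocalized, 1)
  # everything >= 10x threshold apart: nothing colocalizes
  far <- lapply(1:5, function(i) make_traj(xs[[i]] + 10 + 2 * i, dt = 0.08,
                                           id = sprintf("f%d", i),
                                           channel = "705"))
  expect_identical(colocalization_fraction(a, far)$n_colocalized, 0L)
  # same channel label is rejected; empty channel warns and returns 0
  expect_error(colocalization_fraction(a, a), "distinct")
  expect_warning(res0 <- colocalization_fraction(a, list()), "empty")
  expect_equal(res0$fraction_colocalized, 0)
})

test_that("co-bound fraction is recovered on a stationary two-channel field", {
  cfg <- sim_config(n_particles = 100, coloc_fraction = 0.24,
                    motile_fraction = 0, half_life_true = 8900, window = 60,
                    seed = 51)
  sim <- simulate_tightrope_particles(cfg, two_channel = TRUE)
  ch <- vapply(sim$trajectories, `[[`, "", "channel")
  res <- colocalization_fraction(sim$trajectories[ch == "605"],
                                 sim$trajectories[ch == "705"])
  expect_lt(abs(res$fraction_colocalized - 0.24), 0.05)
  expect_lte(res$n_colocalized, min(res$n_channel_a, res$n_channel_b))
})
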