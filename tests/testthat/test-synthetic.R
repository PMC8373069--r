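test_that("config validation names the offending parameter", {
  expect_error(sim_config(frame_rate = 0), "frame_rate")
  expect_error(sim_config(motile_fraction = 1.5), "motile_fraction")
  expect_error(sim_config(alpha_true = 2), "alpha_true")
  expect_error(sim_config(half_life_true = -1), "half_life_true")
  expect_error(sim_config(coloc_fraction = NaN), "coloc_fraction")
  expect_error(sim_config(D_true = Inf), "D_true")
})

test_that("identical seeds give bit-identical simulations", {
  cfg <- sim_config(n_particles = 12, seed = 101, window = 20)
  a <- simulate_tightrope_particles(cfg, two_channel = TRUE)
  b <- simulate_tightrope_particles(cfg, two_channel = TRUE)
  expect_identical(a, b)
  cfg2 <- sim_config(n_particles = 12, seed = 102, window = 20)
  c <- simulate_tightrope_particles(cfg2, two_channel = TRUE)
  expect_false(identical(a$trajectories, c$trajectories))
})

test_that("degenerate mixtures behave as constructed", {
  # no motile particles: variance about the site is localization noise only
  cfg <- sim_config(n_particles = 30, motile_fraction = 0, seed = 5,
                    window = 40, half_life_true = 1e9, loc_noise_sd = 0.03)
  sim <- simulate_tightrope_particles(cfg)
  expect_false(any(sim$truth$is_motile))
  vars <- vapply(sim$trajectories, function(tr) stats::var(tr$positions),
                 numeric(1))
  expect_equal(mean(vars), 0.03^2, tolerance = 0.1)
  # no-dissociation limit: everything right-censored at the window
  expect_true(all(sim$truth$censored))
  lens <- vapply(sim$trajectories, function(tr) max(tr$times), numeric(1))
  expect_true(all(abs(lens - (40 - 1 / 12.5)) < 1 / 12.5 + 1e-9))
})

test_that("simulated lifetimes have the exponential mean", {
  d <- simulate_dwell_times(10000, half_life = 590, seed = 42)
  true_mean <- 590 / log(2)
  se <- true_mean / sqrt(10000)
  expect_lt(abs(mean(d$duration) - true_mean), 3 * se)
  expect_true(all(d$observed))
})

test_that("censoring bookkeeping always sums to n", {
  for (s in 1:5) {
    d <- simulate_dwell_times(200, half_life = 590, window = 300, seed = s)
    expect_identical(sum(d$observed) + sum(!d$observed), 200L)
    expect_true(all(d$duration[!d$observed] == 300))
  }
  cfg <- sim_config(n_particles = 50, seed = 9, window = 30,
                    half_life_true = 40)
  sim <- simulate_tightrope_particles(cfg)
  expect_identical(sum(sim$truth$censored) + sum(!sim$truth$censored), 50L)
})

test_that("Brownian displacement variance matches 2*D*lag", {
  set.seed(77)
  D <- 3.01e-2
  dt <- 1 / 12.5
  inc <- sqrt(2 * D) * diff(tightropekit:::sample_displacement(10000, 1, dt))
  v <- mean(inc^2)
  se <- stats::sd(inc^2) / sqrt(length(inc))
  expect_lt(abs(v - 2 * D * dt), 3 * se)
})

test_that("fGn generator reproduces the analytic autocovariance", {
  set.seed(3)
  H <- 0.595  # alpha = 1.19
  X <- replicate(1500, tightropekit:::fgn_sample(64, H))
  gamma1 <- 0.5 * (2^(2 * H) - 2)
  expect_equal(mean(X^2), 1, tolerance = 0.03)
  expect_equal(mean(X[-64, ] * X[-1, ]), gamma1, tolerance = 0.03)
  # fBm variance grows as t^(2H)
  B <- apply(X, 2, cumsum)
  expect_equal(stats::var(B[32, ]), 32^(2 * H), tolerance = 0.1)
})

test_that("fBm ensemble at alpha = 1 scales like pure Brownian motion", {
  set.seed(11)
  dt <- 1 / 12.5
  # ensemble MSD over 200 trajectories, log-log slope must be 1.00 +/- 0.05
  msds <- replicate(200, {
    tr <- make_motile_track(150, D = 3.01e-2, alpha = 1, dt = dt)
    compute_msd(tr)$msd
  })
  ens <- rowMeans(msds)
  lag_t <- seq_along(ens) * dt
  slope <- ols_oracle(log(lag_t), log(ens))[2]
  expect_equal(slope, 1.00, tolerance = 0.05)
})

test_that("AFM field generator honours weights, curve and noise", {
  curve <- fit_standard_curve(data.frame(mw_kda = c(100, 200),
                                         volume_nm3 = c(200, 400)))
  # single species, zero noise: protein volumes identical and on the curve
  f <- simulate_afm_field(150, 1, curve, n = 20, noise_sd = 0, seed = 1)
  v_prot <- protein_volume_from_complex(f$v_complex_nm3, f$v_dna1_nm3,
                                        f$v_dna2_nm3)
  expect_equal(v_prot, rep(300, 20), tolerance = 1e-12)
  # zero-weight species never drawn
  f2 <- simulate_afm_field(c(100, 200), c(1, 0), curve, n = 200,
                           noise_sd = 5, seed = 2)
  expect_true(all(f2$species == 1))
  expect_error(simulate_afm_field(150, 1, curve, n = -3, noise_sd = 0),
               "n")
  expect_error(simulate_afm_field(c(100, 200), c(0.6, 0.6), curve, 10, 0),
               "weights")
})

test_that("excision time-course generator has the burst shape", {
  # half-rise at ln2 / k_burst in the single-turnover limit
  tc <- simulate_excision_timecourse(10, 0.01, 0, 50,
                                     times = c(0, log(2) / 0.01, 1e6),
                                     noise_sd = 0)
  expect_equal(tc$product_nM, c(0, 5, 10), tolerance = 1e-9)
  # substrate exhaustion clamps the course at the cap
  tc2 <- suppressWarnings(
    simulate_excision_timecourse(60, 0.01, 0.1, 50,
                                 times = c(0, 1e5), noise_sd = 0))
  expect_equal(max(tc2$product_nM), 50)
  expect_true(isTRUE(attr(tc2, "burst_exceeds_substrate")) ||
                max(tc2$product_percent) == 100)
})

test_that("isotherm generator follows the quadratic solution", {
  iso <- simulate_binding_isotherm(4, 8, c(0, 64, 1e6), noise_sd = 0)
  expect_equal(iso$fraction_bound[1], 0)
  expect_equal(iso$fraction_bound[2], bound_dna_oracle(64, 8, 4) / 8,
               tolerance = 1e-9)
  expect_equal(iso$fraction_bound[3], 1, tolerance = 1e-4)
  expect_error(simulate_binding_isotherm(4, 8, c(-1, 2)), "titrant")
})
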