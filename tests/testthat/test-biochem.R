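test_that("lane quantification matches hand arithmetic", {
  # a single bound band carrying the whole lane
  q1 <- quantify_lane(c(bound = 500), background = 0)
  expect_equal(q1$percents$percent, 100)
  # bound = free splits the lane
  q2 <- quantify_lane(c(free = 400, bound = 400))
  expect_equal(q2$percents$percent, c(50, 50))
  # worked example with per-band background
  q3 <- quantify_lane(c(free = 300, bound = 500, supershift = 200),
                      background = 100,
                      groups = list(bound = c("bound", "supershift"),
                                    free = "free"))
  expect_equal(q3$percents$percent[q3$percents$group == "bound"],
               100 * 500 / 700, tolerance = 1e-12)
  # invariance under uniform intensity rescaling
  q4 <- quantify_lane(10 * c(free = 300, bound = 500, supershift = 200),
                      background = 1000,
                      groups = list(bound = c("bound", "supershift"),
                                    free = "free"))
  expect_equal(q4$percents$percent, q3$percents$percent)
  expect_error(quantify_lane(c(a = 10, b = 20), background = 40), "positive")
  expect_error(quantify_lane(c(a = 10), groups = list(g = "zz")), "unknown")
})

test_that("quadratic binding respects mass conservation and saturation", {
  E <- c(0, 0.5, 2, 8, 32, 128, 1e5)
  f <- fraction_bound_quadratic(E, dna_total = 8, kd = 4)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0 & f <= 1))
  expect_equal(f[1], 0)
  expect_equal(f[length(f)], 1, tolerance = 1e-3)
  # bound DNA never exceeds either total
  expect_true(all(f * 8 <= pmax(E, 8) + 1e-9))
  # against the numeric mass-action oracle
  for (e in c(1, 4, 20))
    expect_equal(fraction_bound_quadratic(e, 8, 4),
                 bound_dna_oracle(e, 8, 4) / 8, tolerance = 1e-10)
})

test_that("Kd fit recovers noiseless data and the hyperbolic limit", {
  titr <- c(0, 1, 2, 4, 8, 16, 32, 64)
  iso <- simulate_binding_isotherm(4, 8, titr, noise_sd = 0)
  fit <- fit_quadratic_kd(iso)
  expect_equal(fit$kd, 4, tolerance = 1e-6)
  # with DNA at Kd/100 the quadratic reduces to E/(E + Kd) within 1%
  kd <- 4
  E <- c(0.5, 1, 2, 4, 8, 16, 32)
  f_quad <- fraction_bound_quadratic(E, dna_total = kd / 100, kd = kd)
  expect_equal(f_quad, E / (E + kd), tolerance = 0.01)
  # a flat isotherm is unidentifiable
  flat <- data.frame(titrant_nM = titr, fraction_bound = rep(0.95, 8))
  expect_error(fit_quadratic_kd(flat, dna_total = 8), "identifiab")
})

test_that("Kd recovery is accurate across noise levels", {
  titr <- c(0, 1, 2, 4, 8, 16, 32, 64)
  set.seed(44)
  for (sigma in c(0.01, 0.02, 0.05)) {
    rel_err <- replicate(100, {
      iso <- simulate_binding_isotherm(4, 8, titr, noise_sd = sigma)
      abs(fit_quadratic_kd(iso)$kd - 4) / 4
    })
    expect_lte(stats::median(rel_err), 0.10)
  }
})

test_that("burst fit recovers exact parameters and the no-turnover limit", {
  times <- c(0, 30, 60, 120, 300, 600, 1800, 3600, 7200, 14400)
  tc <- simulate_excision_timecourse(10, 0.01, 0, 50, times, noise_sd = 0)
  fit <- fit_burst_kinetics(tc)
  expect_equal(fit$amplitude, 10, tolerance = 1e-4)
  expect_equal(fit$k_burst, 0.01, tolerance = 1e-4)
  expect_lt(fit$k_ss, 1e-6)
  expect_equal(predict(fit, 0), 0)
  # late-time turnover slope A0 * k_ss recovered within 5%
  tc2 <- simulate_excision_timecourse(10, 0.01, 2e-4, 50, times,
                                      noise_sd = 0)
  fit2 <- fit_burst_kinetics(tc2)
  expect_equal(fit2$amplitude * fit2$k_ss, 10 * 2e-4, tolerance = 0.05)
  # amplitude is bounded by the active-enzyme total
  tc3 <- simulate_excision_timecourse(10, 0.01, 0, 50, times, noise_sd = 0)
  fit3 <- fit_burst_kinetics(tc3, enzyme_total = 9)
  expect_lte(fit3$amplitude, 9 + 1e-9)
})

test_that("stimulation fold reports product and turnover ratios", {
  times <- c(0, 30, 60, 120, 300, 600, 1800, 3600, 7200, 14400)
  tc <- simulate_excision_timecourse(8, 0.01, 2e-5, 50, times, noise_sd = 0)
  same <- stimulation_fold(tc, tc, t_eval = 3600)
  expect_equal(same$fold_product, 1, tolerance = 1e-12)
  # a course scaled 4.5x everywhere gives fold 4.5
  tc45 <- excision_timecourse(tc$time_s, 4.5 * tc$product_percent,
                              substrate_total = 50)
  expect_equal(stimulation_fold(tc, tc45, t_eval = 600)$fold_product, 4.5,
               tolerance = 1e-9)
  # constructed k_ss ratio of 5 is recovered within 5%
  tc_plus <- simulate_excision_timecourse(8, 0.01, 1e-4, 50, times,
                                          noise_sd = 0)
  fold <- stimulation_fold(tc, tc_plus)
  expect_equal(fold$fold_kss, 5, tolerance = 0.05)
  expect_error(stimulation_fold(tc, tc_plus, t_eval = 1e6), "cover")
})
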