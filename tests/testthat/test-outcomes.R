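test_that("baseline-hazard calibration recovers the exponential closed form", {
  p <- snp_panel(0.3, beta_int = 0)
  fr <- build_frame_fixed_genotypes(matrix(0, nrow = 50, ncol = 1))
  hz <- calibrate_baseline_hazard(fr, p, followup = 4, target_incidence = 0.37)
  expect_equal(hz$lambda0, -log(0.63) / 4, tolerance = 1e-8)

  # constant relative hazard: doubling exp(x beta) halves lambda0
  fr1 <- build_frame_fixed_genotypes(matrix(1, nrow = 50, ncol = 1))
  p2 <- snp_panel(0.3, beta_int = 0, beta_main = log(2))
  hz2 <- calibrate_baseline_hazard(fr1, p2, followup = 4, target_incidence = 0.37)
  expect_equal(hz2$lambda0, hz$lambda0 / 2, tolerance = 1e-7)

  expect_error(
    calibrate_baseline_hazard(fr, p, followup = 4, target_incidence = 1.2),
    class = "gbr_invalid_config"
  )
})

test_that("realized event fraction matches the calibration target", {
  set.seed(30)
  p <- draw_panel(20, c(0.2, 0.5), c(0.15, 0.30))
  fr <- build_frame(p, 20000)
  hz <- calibrate_baseline_hazard(fr, p, 4, 0.37)
  co <- randomize_arms(recruit_conventional(fr, 20000))
  rec <- simulate_survival(co, p, hz)
  se <- sqrt(0.37 * 0.63 / 20000)
  expect_lt(abs(mean(rec$event) - 0.37), 3 * se)
})

test_that("the inverse-hazard transform has the exponential closed form", {
  lambda0 <- -log(0.63) / 4
  # U = 0.63 at the baseline rate lands exactly on the 4-year boundary
  expect_equal(survival_time(0.63, lambda0), 4, tolerance = 1e-12)
  # extreme linear predictor drives the time to zero
  expect_lt(survival_time(0.5, lambda0, eta = 50), 1e-15)

  # with all effects zero, uncensored latent times are exponential(lambda0)
  set.seed(31)
  p0 <- snp_panel(c(0.3, 0.4), beta_int = 0)
  fr <- build_frame(p0, 1e5)
  co <- randomize_arms(recruit_conventional(fr, 1e5))
  hz <- hazard_spec(lambda0, followup = 1e9)
  rec <- simulate_survival(co, p0, hz)
  ks <- suppressWarnings(ks.test(rec$time, "pexp", lambda0))
  expect_gt(ks$p.value, 0.001)
  # administrative censoring: event = 0 iff time is the follow-up horizon
  hz4 <- hazard_spec(lambda0, followup = 4)
  rec4 <- simulate_survival(co, p0, hz4)
  expect_true(all(rec4$time[rec4$event == 0] == 4))
  expect_true(all(rec4$time[rec4$event == 1] < 4))
})

test_that("quantitative outcomes compose treatment, marginal and interaction terms", {
  p <- snp_panel(0.3, beta_int = 0.03)
  co <- make_test_cohort(p, frame_size = 400, n = 100, seed = 32)
  y <- simulate_quantitative(co, p, treatment_main = 0, resid_sd = 0)
  expect_equal(y, 0.03 * co$grs * co$arm)

  # pure-noise null
  set.seed(33)
  p0 <- snp_panel(0.3, beta_int = 0)
  co0 <- make_test_cohort(p0, frame_size = 60000, n = 50000, seed = 33)
  y0 <- simulate_quantitative(co0, p0, resid_sd = 2)
  expect_lt(abs(mean(y0)), 4 * 2 / sqrt(50000))
  expect_equal(sd(y0), 2, tolerance = 0.02)
})

test_that("measurement error achieves the configured reliability r2", {
  set.seed(34)
  y <- rnorm(1e5)
  expect_identical(add_measurement_error(y, 1)$y_obs, y)

  out <- add_measurement_error(y, 0.8)
  expect_identical(out$y_true, y)              # never changes the truth
  expect_equal(cor(out$y_obs, out$y_true)^2, 0.8, tolerance = 0.01)

  # error-variance algebra: r2 = 0.4 implies var(e) = 1.5 var(y)
  out4 <- add_measurement_error(y, 0.4)
  expect_equal(var(out4$y_obs - y) / var(y), 1.5, tolerance = 0.05)

  expect_error(add_measurement_error(y, 0), class = "gbr_invalid_config")
  expect_error(add_measurement_error(y, 1.1), class = "gbr_invalid_config")
  expect_error(add_measurement_error(rep(1, 10), 0.8),
               class = "gbr_degenerate_input")
})
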