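test_that("Zero/One power counts strict rejections", {
  expect_equal(power_zero_one(c(0.01, 0.20, 0.04), 0.05)$power, 2 / 3)
  # boundary p exactly at alpha does not reject
  expect_equal(power_zero_one(0.05, 0.05)$power, 0)
  expect_equal(power_zero_one(rep(0, 10), 0.05)$power, 1)
  est <- power_zero_one(c(0.01, 0.2, 0.04, NA), 0.05)
  expect_equal(est$n_used, 3)
  expect_equal(est$mc_se, sqrt((2 / 3) * (1 / 3) / 3))
  expect_error(power_zero_one(numeric(0)), class = "gbr_invalid_input")
})

test_that("Standard-Error method power follows the normal formula", {
  expect_equal(power_se(0, 1, 0.05)$power, pnorm(-qnorm(0.975)),
               tolerance = 1e-10)
  expect_equal(power_se(qnorm(0.975), 1, 0.05)$power, 0.5, tolerance = 1e-10)
  expect_equal(power_se(2.8016, 1, 0.05)$power, 0.800, tolerance = 5e-4)
  expect_error(power_se(1, 0), class = "gbr_invalid_input")
})

test_that("scenario configs validate their invariants", {
  expect_error(scenario_config(alpha = 1.5), class = "gbr_invalid_config")
  expect_error(scenario_config(iterations = 0), class = "gbr_invalid_config")
  expect_error(scenario_config(n_trial = 200, frame_size = 100),
               class = "gbr_invalid_config")
  expect_error(scenario_config(freqs = 0.3), class = "gbr_invalid_config")
})

test_that("power estimation is reproducible from the scenario seed", {
  cfg <- scenario_config(design = "gbr", outcome = "quantitative",
                         frame_size = 500, n_trial = 100, k = 5,
                         effect_range = c(0.1, 0.2), iterations = 30,
                         seed = 99)
  a <- estimate_power(cfg, keep_fits = TRUE)
  b <- estimate_power(cfg, keep_fits = TRUE)
  expect_identical(a$fits, b$fits)
  expect_identical(a$zero_one$power, b$zero_one$power)
  expect_identical(a$panel$freqs, b$panel$freqs)
  expect_equal(a$zero_one$n_used, 30)
})

test_that("type-I calibration holds at a small scale for both designs", {
  for (d in c("conventional", "gbr")) {
    cfg <- scenario_config(design = d, outcome = "quantitative",
                           frame_size = 600, n_trial = 150, k = 5,
                           effect_range = c(0, 0), iterations = 400,
                           seed = 7)
    est <- estimate_power(cfg)
    expect_lt(abs(est$zero_one$power - 0.05), 0.04)
  }
})

test_that("sample-size search inverts a known power curve", {
  cfg <- scenario_config(frame_size = 20000, iterations = 10, seed = 1)
  mock <- function(n) 1 - exp(-n / 1000)
  # analytic 80% crossing at 1609.44: smallest multiple of 10 above is 1610
  s <- find_sample_size(cfg, 0.8, bracket = c(100, 10000), resolution = 10,
                        power_fn = mock)
  expect_true(s$reached)
  expect_equal(s$n, 1610)

  # degenerate target returns the minimum allowed n
  s0 <- find_sample_size(cfg, 0, bracket = c(100, 10000), power_fn = mock)
  expect_equal(s0$n, 100)

  # unreachable target is a result, not an exception
  s_bad <- find_sample_size(cfg, 0.95, bracket = c(10, 100), power_fn = mock)
  expect_false(s_bad$reached)
  expect_true(is.na(s_bad$n))
})

test_that("isotonic smoothing makes the reported power curve monotone", {
  cfg <- scenario_config(frame_size = 20000, iterations = 10, seed = 1)
  set.seed(50)
  noisy <- function(n) min(1, max(0, 1 - exp(-n / 1000) + rnorm(1, 0, 0.05)))
  s <- find_sample_size(cfg, 0.8, bracket = c(100, 10000), resolution = 10,
                        power_fn = noisy)
  expect_true(s$reached)
  expect_true(all(diff(s$evaluations$smoothed) >= -1e-12))
  expect_lt(abs(s$n - 1610) / 1610, 0.25) # noise moves the crossing a little
})
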