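test_that("noise-free step tables satisfy the placement model exactly", {
  cfg <- synthetic_gait_config(n_strides = 50, sigma_eps = 0, seed = 9)
  truth <- simulate_step_table(cfg)
  expect_equal(
    truth$fp, cfg$beta_pos * truth$com_pos + cfg$beta_vel * truth$com_vel
  )
  fit <- fit_foot_placement_model(truth)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(fit$fp_error_sd, 1e-12)
})

test_that("with zero gains the placement sd reflects sigma_eps", {
  cfg <- synthetic_gait_config(
    n_strides = 1000, beta_pos = 0, beta_vel = 0, sigma_eps = 0.005, seed = 21
  )
  truth <- simulate_step_table(cfg)
  expect_equal(truth$fp, truth$eps)
  expect_gt(sd(truth$fp), 0.004)
  expect_lt(sd(truth$fp), 0.006)
})

test_that("seeding is reproducible and different seeds differ", {
  a <- simulate_step_table(synthetic_gait_config(n_strides = 40, seed = 5))
  b <- simulate_step_table(synthetic_gait_config(n_strides = 40, seed = 5))
  c <- simulate_step_table(synthetic_gait_config(n_strides = 40, seed = 6))
  expect_identical(a$fp, b$fp)
  expect_identical(a$t_hs, b$t_hs)
  expect_false(any(a$eps == c$eps))
})

test_that("config validation rejects degenerate settings", {
  expect_error(synthetic_gait_config(n_strides = 20), "at least 35")
  expect_error(synthetic_gait_config(stride_time_mean = 0), "positive")
  expect_error(synthetic_gait_config(sigma_eps = -1), "non-negative")
})

test_that("stride time and step width statistics match the configuration", {
  cfg <- synthetic_gait_config(n_strides = 1000, seed = 13)
  truth <- simulate_step_table(cfg)
  st <- truth$stride_time[!is.na(truth$stride_time)]
  expect_equal(mean(st), cfg$stride_time_mean, tolerance = 0.01)
  expect_equal(sd(st), cfg$stride_time_sd, tolerance = 0.3)
  expect_equal(mean(truth$step_width), cfg$step_width_mean, tolerance = 0.01)
})

test_that("rendering a noise-free walker gives exactly periodic signals", {
  cfg <- synthetic_gait_config(
    n_strides = 40, stride_time_sd = 0, sigma_eps = 0,
    com_sway_sd = 0, com_vel_sd = 0, seed = 1
  )
  ts <- render_continuous(simulate_step_table(cfg), cfg)
  period <- round(cfg$stride_time_mean * cfg$sample_rate) # samples per stride
  # compare interior cycles, away from the lead-in and tail transients
  i0 <- 10L * period
  i1 <- 25L * period
  for (col in c("heel_L_ml", "heel_L_ap", "heel_L_vert", "thorax_ml")) {
    x <- ts[[col]]
    expect_lt(max(abs(x[(i0 + period):(i1 + period)] - x[i0:i1])), 1e-9)
  }
})

test_that("reference series have their stated structure", {
  x <- simulate_reference_series("periodic", 1000, period = 100)
  expect_lt(max(abs(x[101:1000] - x[1:900])), 1e-12)

  y <- simulate_reference_series("logistic_map", 2000, r = 4, x0 = 0.3)
  expect_true(all(y > 0 & y < 1))
  expect_gt(min(abs(diff(y))), 0) # non-repeating consecutive iterates
  expect_error(simulate_reference_series("logistic_map", 500), ">= 2000")

  z0 <- simulate_reference_series(
    "noisy_limit_cycle", 1000, jitter_sd = 0, seed = 4
  )
  expect_equal(z0, simulate_reference_series("periodic", 1000))
  z1 <- simulate_reference_series(
    "noisy_limit_cycle", 1000, jitter_sd = 0.05, seed = 4
  )
  expect_gt(sd(z1 - z0), 0)

  expect_error(simulate_reference_series("brownian", 100))
})
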