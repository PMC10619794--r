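test_that("an exact linear placement law is recovered perfectly", {
  withr::with_seed(1, {
    d <- tibble::tibble(
      com_pos = rnorm(60, 0, 0.01),
      com_vel = rnorm(60, 0, 0.05),
      fp = 1.5 * com_pos + 0.3 * com_vel
    )
  })
  fit <- fit_foot_placement_model(d)
  expect_equal(fit$beta_pos, 1.5, tolerance = 1e-10)
  expect_equal(fit$beta_vel, 0.3, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(fit$fp_error_sd, 1e-14)
  expect_lt(abs(mean(fit$residuals)), 1e-12)
})

test_that("coefficients and R^2 match a normal-equations oracle", {
  truth <- simulate_step_table(synthetic_gait_config(n_strides = 300, seed = 42))
  fit <- fit_foot_placement_model(truth)
  d <- truth
  oracle <- ols_normal_equations(
    d$fp - mean(d$fp),
    cbind(d$com_pos - mean(d$com_pos), d$com_vel - mean(d$com_vel))
  )
  expect_equal(fit$beta_pos, oracle$beta[2], tolerance = 1e-10)
  expect_equal(fit$beta_vel, oracle$beta[3], tolerance = 1e-10)
  expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-10)
})

test_that("pure-noise placement has near-zero explained variance", {
  truth <- simulate_step_table(synthetic_gait_config(
    n_strides = 1000, beta_pos = 0, beta_vel = 0, seed = 77
  ))
  fit <- fit_foot_placement_model(truth)
  expect_lt(fit$r_squared, 0.02)
})

test_that("degenerate fits are refused", {
  d <- tibble::tibble(com_pos = rnorm(30), com_vel = rnorm(30), fp = rnorm(30))
  expect_error(fit_foot_placement_model(d[1:5, ]), "at least 10")
  d$com_vel <- 1
  expect_error(fit_foot_placement_model(d), "singular")
  d$com_vel <- c(NA, rnorm(29))
  expect_error(fit_foot_placement_model(d), "non-finite")
})

test_that("R^2 is scale-invariant and the error sd is equivariant", {
  truth <- simulate_step_table(synthetic_gait_config(n_strides = 100, seed = 31))
  fit <- fit_foot_placement_model(truth)

  scaled <- truth
  scaled$com_pos <- scaled$com_pos * 3.7
  scaled$com_vel <- scaled$com_vel * 0.2
  fit2 <- fit_foot_placement_model(scaled)
  expect_equal(fit2$r_squared, fit$r_squared, tolerance = 1e-10)
  expect_equal(fit2$fp_error_sd, fit$fp_error_sd, tolerance = 1e-12)

  scaled_fp <- truth
  scaled_fp$fp <- scaled_fp$fp * 2.5
  fit3 <- fit_foot_placement_model(scaled_fp)
  expect_equal(fit3$fp_error_sd, 2.5 * fit$fp_error_sd, tolerance = 1e-10)
})

test_that("the variance decomposition holds on demeaned data", {
  truth <- simulate_step_table(synthetic_gait_config(n_strides = 150, seed = 4))
  fit <- fit_foot_placement_model(truth)
  fp_dm <- truth$fp - mean(truth$fp)
  ss_tot <- sum(fp_dm^2)
  explained <- ss_tot - sum(fit$residuals^2)
  expect_equal(
    sum(fit$residuals^2) + explained, ss_tot,
    tolerance = 1e-10 * ss_tot
  )
  # in sd terms: error variance plus explained variance equals total variance
  n <- fit$n_steps
  expect_equal(
    fit$fp_error_sd^2 + explained / (n - 1), ss_tot / (n - 1),
    tolerance = 1e-10
  )
})

test_that("adding placement noise does not increase expected R^2", {
  r2 <- vapply(1:20, function(s) {
    truth <- simulate_step_table(synthetic_gait_config(n_strides = 200, seed = s))
    base <- fit_foot_placement_model(truth)$r_squared
    noisy <- truth
    noisy$fp <- noisy$fp + withr::with_seed(1000 + s, rnorm(nrow(noisy), 0, 0.005))
    c(base, fit_foot_placement_model(noisy)$r_squared)
  }, numeric(2))
  expect_lt(mean(r2[2, ]), mean(r2[1, ]))
  # and the degradation is systematic across seeds
  expect_gt(mean(r2[1, ] > r2[2, ]), 0.9)
})

test_that("block summaries aggregate the way conditions are reported", {
  f <- tibble::tibble(
    beta_pos = c(1.4, 1.6), beta_vel = c(0.25, 0.35),
    r_squared = c(0.2, 0.4), fp_error_sd = c(0.004, 0.006),
    n_steps = c(60L, 60L), n_strides = c(30, 30)
  )
  s <- summarize_blocks(f, "mean_over_blocks")
  expect_equal(s$r_squared, 0.3)
  expect_equal(s$beta_pos, 1.5)
  expect_equal(s$n_blocks, 2L)

  one <- fit_foot_placement_model(
    simulate_step_table(synthetic_gait_config(n_strides = 35, seed = 2))
  )
  s1 <- summarize_blocks(list(one), "mean_over_blocks")
  expect_equal(s1$r_squared, one$r_squared)

  expect_equal(summarize_blocks(f, "first30")$r_squared, 0.2)
  expect_equal(summarize_blocks(f, "last30")$r_squared, 0.4)
  expect_error(summarize_blocks(list()), "empty")
})

test_that("tidy, glance and augment expose the fit in broom form", {
  fit <- fit_foot_placement_model(
    simulate_step_table(synthetic_gait_config(n_strides = 50, seed = 12))
  )
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "com_pos", "com_vel"))
  expect_true(all(c("estimate", "std.error", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$beta_pos, fit$beta_pos)
  au <- augment(fit)
  expect_equal(nrow(au), fit$n_steps)
  expect_equal(au$fp - au$.fitted, au$.resid, tolerance = 1e-12)
  expect_s3_class(autoplot(fit), "ggplot")
})
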