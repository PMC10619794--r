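test_that("step width follows from heel geometry", {
  # symmetric noise-free walker: heels at -0.05 / +0.05 m at midstance
  cfg <- synthetic_gait_config(
    n_strides = 40, stride_time_sd = 0, sigma_eps = 0,
    com_sway_sd = 0, com_vel_sd = 0, seed = 1
  )
  ts <- render_continuous(simulate_step_table(cfg), cfg)
  st <- build_stride_table(ts, detect_heelstrikes(ts), run_config())
  expect_equal(unique(round(st$step_width, 6)), 0.10)
})

test_that("measured step variables track the generator truth", {
  s <- rendered_session(300, seed = 42)
  ev <- compute_sampling_instants(detect_heelstrikes(s$ts))
  st <- build_stride_table(s$ts, ev, run_config())
  tt <- s$truth[2:(nrow(s$truth) - 1), ] # table drops first and last steps
  expect_equal(nrow(st), nrow(tt))

  # foot placement at midstance equals the truth-table placement to 1e-3 m
  mirror <- ifelse(tt$side == "R", 1, -1)
  expect_lt(max(abs(mirror * st$fp_raw - tt$step_width)), 1e-3)
  expect_lt(max(abs(st$step_width - tt$step_width)), 1e-3)

  # demeaned analysis columns correlate > 0.99 with identically demeaned truth
  for (col in c("fp", "com_pos", "com_vel")) {
    truth_dm <- demean_like_blocks(tt[[col]], st$block, st$side)
    expect_gt(cor(st[[col]], truth_dm), 0.99)
  }

  # stride times match the truth
  ok <- !is.na(st$stride_time)
  expect_lt(max(abs(st$stride_time[ok] - tt$stride_time[ok])), 0.03)
})

test_that("foot placement demeans to zero within every block", {
  s <- rendered_session(100, seed = 8)
  st <- build_stride_table(
    s$ts, detect_heelstrikes(s$ts), run_config(block_size = 30)
  )
  means <- st |>
    dplyr::filter(!is.na(block)) |>
    dplyr::group_by(block) |>
    dplyr::summarise(m = mean(fp))
  expect_lt(max(abs(means$m)), 1e-12)
})

test_that("blocks are complete 30-stride groups and partition the strides", {
  s <- rendered_session(80, seed = 15)
  ev <- compute_sampling_instants(detect_heelstrikes(s$ts))
  # condition window trimmed so exactly 65 strides (130 steps) fall inside it
  steps <- ev$steps
  end_t <- steps$t_hs[131L] + 1e-3 # steps 2..131 of the table -> 65 strides
  cfg <- run_config(
    condition_plan = tibble::tibble(condition = "w", start = 0, end = end_t)
  )
  st <- build_stride_table(s$ts, ev, cfg)
  inside <- dplyr::filter(st, !is.na(condition))
  expect_equal(max(inside$stride), 65L)
  expect_equal(max(inside$block, na.rm = TRUE), 2L)
  # 5 trailing strides remain unassigned to any block
  expect_equal(sum(is.na(inside$block)), 10L)
  # block labels partition: each block holds exactly 60 steps
  expect_equal(as.integer(table(inside$block)), c(60L, 60L))
})

test_that("strides flagged by the stride-time gate are excluded from fits", {
  s <- rendered_session(60, seed = 19)
  st <- build_stride_table(s$ts, detect_heelstrikes(s$ts), run_config())
  st$stride_time[5] <- 3.5
  st$flag_stride_time[5] <- TRUE
  fit <- fit_foot_placement_model(st)
  expect_equal(fit$n_steps, nrow(st) - 1L)
})
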