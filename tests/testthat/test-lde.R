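fake_events <- function(hs_L) {
  structure(list(heelstrikes_L = hs_L), class = "gait_events")
}

test_that("time normalization maps strides onto the normalized grid", {
  # 20 strides of exactly 1 s at 100 Hz: grid points coincide with samples
  time <- seq(0, 25, by = 0.01)
  x <- sin(2 * pi * time) + 0.3 * cos(4 * pi * time)
  ev <- fake_events(seq(1, 21, by = 1))
  y <- time_normalize(x, time, ev, lde_params())
  expect_length(y, 2000L)
  expect_equal(as.numeric(y[1:2000]), x[time >= 1 & time < 21], tolerance = 1e-9)

  # variable stride times still force length n_strides * 100
  ev2 <- fake_events(cumsum(c(1, runif(30, 0.9, 1.3))))
  y2 <- time_normalize(x, time, ev2, lde_params())
  expect_length(y2, 3000L)
  expect_equal(attr(y2, "n_strides"), 30L)

  # cubic interpolation reproduces a linear ramp exactly
  ramp <- 0.5 * time - 2
  y3 <- time_normalize(ramp, time, ev2, lde_params())
  grid_t <- 1 + (seq_len(3000) - 1) * (max(ev2$heelstrikes_L) - 1) / 3000
  expect_equal(as.numeric(y3), 0.5 * grid_t - 2, tolerance = 1e-9)

  expect_error(
    time_normalize(x, time, fake_events(1:5), lde_params()),
    "at least 10 strides"
  )
})

test_that("delay embedding has the stated geometry", {
  p <- lde_params(embedding_dim = 6, delay = 25)
  x <- rnorm(200)
  emb <- delay_embed(x, p)
  expect_equal(dim(emb), c(75L, 6L))

  p1 <- lde_params(embedding_dim = 1, delay = 25)
  expect_equal(as.numeric(delay_embed(x, p1)), x)

  # index arithmetic against a literal reconstruction
  y <- simulate_reference_series("logistic_map", 2000)
  p2 <- lde_params(embedding_dim = 4, delay = 3)
  emb2 <- delay_embed(y, p2)
  for (i in c(1L, 500L, nrow(emb2))) {
    expect_identical(emb2[i, ], y[i + 3 * (0:3)])
  }

  expect_error(delay_embed(rnorm(100), p), "too short")
})

test_that("the divergence slope is an exact least-squares line fit", {
  expect_equal(lde_slope((0:99) * 0.01, 50), 0.01, tolerance = 1e-12)
  expect_equal(lde_slope(rep(2.5, 100), 50), 0)

  withr::with_seed(3, curve <- 0.02 * (0:99) + 1e-4 * (0:99)^2)
  k <- 0:49
  fit <- lm(curve[1:50] ~ k)
  expect_equal(lde_slope(curve, 50), unname(coef(fit)[2]), tolerance = 1e-12)

  expect_error(lde_slope(1:10, 20), "exceeds")
})

test_that("neighbour search and curve agree with the brute-force oracle", {
  p <- lde_params(
    samples_per_stride = 100, embedding_dim = 3, delay = 5,
    n_neighbors = 3, theiler_window = 10, horizon = 30, fit_range = 10
  )
  x <- simulate_reference_series(
    "noisy_limit_cycle", 450, period = 50, jitter_sd = 0.05, seed = 17
  )
  res <- compute_lde(x, p)
  oracle <- brute_force_lde(x, p)
  expect_identical(res$pairs$reference, oracle$pairs_i)
  expect_identical(res$pairs$neighbor, oracle$pairs_j)
  expect_equal(res$curve, oracle$curve, tolerance = 1e-12)
  expect_equal(res$lde, oracle$lde, tolerance = 1e-12)
})

test_that("the Theiler window is respected by every selected pair", {
  p <- lde_params(
    embedding_dim = 2, delay = 1, n_neighbors = 5,
    theiler_window = 10, horizon = 50, fit_range = 10
  )
  x <- simulate_reference_series("logistic_map", 2500)
  res <- compute_lde(x, p)
  expect_true(all(abs(res$pairs$reference - res$pairs$neighbor) >= 10))
  # and every pair is trackable for the full horizon
  n_pts <- 2500 - 1
  expect_true(all(res$pairs$neighbor + p$horizon - 1 <= n_pts))
})

test_that("rescaling the signal shifts the curve by log(c) and keeps the exponent", {
  p <- lde_params(
    embedding_dim = 3, delay = 5, n_neighbors = 3,
    theiler_window = 10, horizon = 30, fit_range = 10
  )
  x <- simulate_reference_series(
    "noisy_limit_cycle", 600, period = 50, jitter_sd = 0.05, seed = 23
  )
  a <- compute_lde(x, p)
  b <- compute_lde(3 * x, p)
  expect_equal(b$curve - a$curve, rep(log(3), p$horizon), tolerance = 1e-10)
  expect_equal(b$lde, a$lde, tolerance = 1e-10)
})

test_that("stronger cycle jitter raises the divergence exponent", {
  p <- lde_params(
    embedding_dim = 5, delay = 10, n_neighbors = 5,
    theiler_window = 25, horizon = 200, fit_range = 25
  )
  lo <- compute_lde(simulate_reference_series(
    "noisy_limit_cycle", 3000, period = 50, jitter_sd = 0.01, seed = 42
  ), p)
  hi <- compute_lde(simulate_reference_series(
    "noisy_limit_cycle", 3000, period = 50, jitter_sd = 0.05, seed = 42
  ), p)
  expect_gt(hi$lde, lo$lde)
})

test_that("series too short for the horizon are refused", {
  p <- lde_params(horizon = 1000)
  expect_error(compute_lde(rnorm(500), p), "too short")
})
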