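# Independent oracles used across the suite. These deliberately use naive
# loops and textbook formulas, not the package's vectorised code paths.

# O(n^2) brute-force divergence estimator: neighbour sets by direct pairwise
# distances (Theiler + horizon admissibility, ties by smaller index), curve
# by per-pair tracking.
brute_force_lde <- function(x, params) {
  m <- params$embedding_dim
  d <- params$delay
  n <- length(x) - d * (m - 1L)
  emb <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) emb[i, j] <- x[i + (j - 1L) * d]
  }
  n_track <- n - params$horizon + 1L
  pairs_i <- integer()
  pairs_j <- integer()
  for (i in seq_len(n_track)) {
    dist_ij <- rep(Inf, n_track)
    for (j in seq_len(n_track)) {
      if (abs(i - j) < params$theiler_window) next
      dist_ij[j] <- sqrt(sum((emb[i, ] - emb[j, ])^2))
    }
    adm <- which(is.finite(dist_ij))
    if (length(adm) < params$n_neighbors) next
    o <- order(dist_ij, seq_len(n_track))
    sel <- o[seq_len(params$n_neighbors)]
    pairs_i <- c(pairs_i, rep(i, params$n_neighbors))
    pairs_j <- c(pairs_j, sel)
  }
  curve <- numeric(params$horizon)
  for (s in seq_len(params$horizon) - 1L) {
    total <- 0
    for (p in seq_along(pairs_i)) {
      dd <- sqrt(sum((emb[pairs_i[p] + s, ] - emb[pairs_j[p] + s, ])^2))
      total <- total + log(max(dd, params$dist_floor))
    }
    curve[s + 1L] <- total / length(pairs_i)
  }
  k <- seq_len(params$fit_range) - 1
  y <- curve[seq_len(params$fit_range)]
  list(
    pairs_i = pairs_i, pairs_j = pairs_j, curve = curve,
    lde = sum((k - mean(k)) * (y - mean(y))) / sum((k - mean(k))^2)
  )
}

# normal-equations OLS with intercept; returns coefficients and R^2
ols_normal_equations <- function(y, X) {
  Xi <- cbind(1, X)
  beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
  res <- y - Xi %*% beta
  ss_tot <- sum((y - mean(y))^2)
  list(beta = as.numeric(beta), r_squared = 1 - sum(res^2) / ss_tot)
}

# rendered synthetic session, cached per (n_strides, seed) within a run
rendered_session <- local({
  cache <- list()
  function(n_strides, seed, ...) {
    key <- paste(n_strides, seed, ...)
    if (is.null(cache[[key]])) {
      cfg <- synthetic_gait_config(n_strides = n_strides, seed = seed, ...)
      truth <- simulate_step_table(cfg)
      cache[[key]] <<- list(
        config = cfg, truth = truth, ts = render_continuous(truth, cfg)
      )
    }
    cache[[key]]
  }
})

# match detected events to ground truth within a tolerance; returns counts
match_events <- function(detected, truth, tol = 0.05) {
  used <- logical(length(truth))
  tp <- 0L
  err <- numeric()
  for (t_d in detected) {
    i <- which(!used & abs(truth - t_d) <= tol)
    if (length(i) > 0L) {
      i <- i[which.min(abs(truth[i] - t_d))]
      used[i] <- TRUE
      tp <- tp + 1L
      err <- c(err, t_d - truth[i])
    }
  }
  list(
    tp = tp, fp = length(detected) - tp, fn = length(truth) - tp,
    f1 = 2 * tp / (2 * tp + (length(detected) - tp) + (length(truth) - tp)),
    max_abs_err = if (length(err)) max(abs(err)) else NA_real_
  )
}

# demean a truth column the same way build_stride_table demeans measured
# columns (per condition-block-side over unflagged rows); truth tables have
# one condition and no flags, so per (block, side)
demean_like_blocks <- function(x, block, side) {
  g <- paste(ifelse(is.na(block), -1L, block), side)
  x - ave(x, g)
}
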