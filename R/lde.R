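#' Local divergence exponent parameters
#'
#' Constants of the local divergence exponent (local dynamic stability)
#' estimator. The defaults implement the standard gait parameterisation:
#' time-normalize so a stride averages 100 samples, reconstruct a
#' six-dimensional state space from 25-sample delayed copies, take the five
#' nearest neighbours of each point at a temporal separation of at least
#' half an average stride (50 normalized samples), track divergence for 1000
#' samples and fit the exponent over the first 50 samples (half a stride) of
#' the averaged logarithmic divergence curve.
#'
#' @param samples_per_stride samples per average stride after normalization.
#' @param embedding_dim embedding dimension.
#' @param delay embedding delay, samples.
#' @param n_neighbors nearest neighbours tracked per reference point.
#' @param theiler_window minimum temporal separation `|i - j|` between a
#'   reference point and its neighbours, samples.
#' @param horizon divergence tracking length, samples.
#' @param fit_range number of leading curve samples the exponent line is
#'   fitted through.
#' @param dist_floor lower bound applied to distances before taking the log,
#'   keeping exactly recurrent (zero-distance) pairs finite.
#' @return A list of class `lde_params`.
#' @export
lde_params <- function(samples_per_stride = 100L,
                       embedding_dim = 6L,
                       delay = 25L,
                       n_neighbors = 5L,
                       theiler_window = samples_per_stride %/% 2L,
                       horizon = 1000L,
                       fit_range = 50L,
                       dist_floor = 1e-12) {
  p <- list(
    samples_per_stride = as.integer(samples_per_stride),
    embedding_dim = as.integer(embedding_dim),
    delay = as.integer(delay),
    n_neighbors = as.integer(n_neighbors),
    theiler_window = as.integer(theiler_window),
    horizon = as.integer(horizon),
    fit_range = as.integer(fit_range),
    dist_floor = dist_floor
  )
  stopifnot(
    p$samples_per_stride > 0L, p$embedding_dim >= 1L, p$delay >= 1L,
    p$n_neighbors >= 1L, p$theiler_window >= 1L, p$horizon >= 2L,
    p$fit_range >= 2L, p$fit_range <= p$horizon, p$dist_floor > 0
  )
  class(p) <- "lde_params"
  p
}

#' Time-normalize a signal to a fixed number of samples per stride
#'
#' Resamples the whole signal in one pass onto a uniform grid spanning the
#' first to the last heelstrike of the reference (left) leg, with a total
#' length of `n_strides * samples_per_stride`. Each stride is therefore 100
#' samples long *on average*; there is no per-stride warping. Cubic
#' interpolation is used, so values at coinciding grid points are preserved
#' exactly and polynomial signals are reproduced to machine precision.
#'
#' @param x scalar signal sampled at `time`.
#' @param time sample times, s.
#' @param events a `gait_events` object; its left heelstrikes delimit the
#'   strides.
#' @param params an [lde_params()].
#' @return Numeric vector of length `n_strides * samples_per_stride`, with
#'   attribute `n_strides`.
#' @export
time_normalize <- function(x, time, events, params = lde_params()) {
  stopifnot(length(x) == length(time), inherits(events, "gait_events"))
  hs <- events$heelstrikes_L
  n_strides <- length(hs) - 1L
  if (n_strides < 10L) {
    abort(sprintf(
      "at least 10 strides are required for time normalization (got %d).",
      n_strides
    ))
  }
  out_len <- n_strides * params$samples_per_stride
  t0 <- hs[1L]
  t1 <- hs[length(hs)]
  grid <- t0 + (seq_len(out_len) - 1L) * (t1 - t0) / out_len
  y <- spline(time, x, xout = grid, method = "fmm")$y
  attr(y, "n_strides") <- n_strides
  y
}

#' Delay embedding
#'
#' Reconstructs a state space from a scalar series using time-delayed
#' copies: point `i` is `(x[i], x[i + delay], ..., x[i + delay * (dim - 1)])`.
#'
#' @param x scalar series.
#' @param params an [lde_params()] (only `embedding_dim` and `delay` used).
#' @return Matrix with `length(x) - delay * (dim - 1)` rows and `dim`
#'   columns.
#' @export
delay_embed <- function(x, params = lde_params()) {
  m <- params$embedding_dim
  d <- params$delay
  span <- d * (m - 1L)
  n <- length(x) - span
  if (n < 1L) {
    abort(sprintf(
      "series too short for embedding: need more than %d samples, got %d.",
      span, length(x)
    ))
  }
  vapply(seq_len(m), function(j) x[(1:n) + (j - 1L) * d], numeric(n))
}

# n_neighbors nearest admissible neighbours for each reference point.
# Candidates are preselected with a cross-product distance expansion, then
# their distances recomputed coordinate-wise so that selection and
# tie-breaking (smallest distance, then smallest index) are bit-identical to
# a direct O(n^2) computation.
nearest_neighbors <- function(emb, n_track, params) {
  k <- params$n_neighbors
  w <- params$theiler_window
  m <- n_track # admissible indices: 1..n_track
  g <- emb[seq_len(m), , drop = FALSE]
  sq <- rowSums(g^2)
  pre <- min(m, 4L * k + 16L) # margin over k against preselection rounding
  nb <- matrix(NA_integer_, nrow = m, ncol = k)
  chunk <- 512L
  for (lo in seq(1L, m, by = chunk)) {
    hi <- min(lo + chunk - 1L, m)
    idx <- lo:hi
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(g[idx, , drop = FALSE], g)
    for (r in seq_along(idx)) {
      i <- idx[r]
      row <- d2[r, ]
      row[abs(seq_len(m) - i) < w] <- Inf
      cand <- order(row)[seq_len(min(pre, m))]
      cand <- cand[is.finite(row[cand])]
      if (length(cand) < k) {
        nb[i, ] <- NA_integer_
        next
      }
      # exact recomputation for deterministic ordering
      dx <- g[cand, , drop = FALSE] -
        matrix(g[i, ], nrow = length(cand), ncol = ncol(g), byrow = TRUE)
      dexact <- sqrt(rowSums(dx^2))
      o <- order(dexact, cand)
      nb[i, ] <- cand[o[seq_len(k)]]
    }
  }
  nb
}

#' Compute the local divergence exponent
#'
#' Estimates the local divergence exponent (the short-term finite-time
#' analogue of the largest Lyapunov exponent) of a scalar signal, most
#' commonly the time-normalized mediolateral CoM velocity:
#'
#' 1. delay-embed the signal ([delay_embed()]);
#' 2. restrict reference points to those with at least `horizon` future
#'    samples;
#' 3. for each reference point find the `n_neighbors` nearest points by
#'    Euclidean distance, subject to a temporal separation of at least
#'    `theiler_window` samples; each neighbour must itself be trackable for
#'    the full horizon (pairs are never partially tracked); distance ties are
#'    broken by the smaller index;
#' 4. average the natural-log Euclidean divergence
#'    `ln ||x[i + s] - x[j + s]||` over all pairs for `s = 0 ... horizon - 1`
#'    (distances floored at `dist_floor`);
#' 5. fit a least-squares line through the first `fit_range` samples of that
#'    curve ([lde_slope()]); its slope is the exponent.
#'
#' Reference points that do not admit `n_neighbors` valid neighbours are
#' skipped and counted. The exponent is in ln-units per normalized sample;
#' multiply by `samples_per_stride` for the per-stride value.
#'
#' @param x scalar series. Either a raw signal accompanied by `time` and
#'   `events` (it is then passed through [time_normalize()]) or an already
#'   normalized series (leave `time` and `events` `NULL`).
#' @param params an [lde_params()].
#' @param time,events see [time_normalize()].
#' @return An object of class `lde_result`: list with `curve` (mean log
#'   divergence, length `horizon`), `lde`, `lde_per_stride`, `n_pairs_used`,
#'   `n_skipped`, `pairs` (the reference/neighbour index pairs used) and
#'   `params`.
#' @export
#' @examples
#' x <- simulate_reference_series("logistic_map", 2000)
#' p <- lde_params(
#'   embedding_dim = 2, delay = 1, theiler_window = 10,
#'   horizon = 50, fit_range = 10
#' )
#' compute_lde(x, params = p)$lde # close to ln 2
compute_lde <- function(x, params = lde_params(), time = NULL, events = NULL) {
  if (!is.null(events)) {
    x <- time_normalize(x, time, events, params)
  }
  emb <- delay_embed(x, params)
  n_pts <- nrow(emb)
  n_track <- n_pts - params$horizon + 1L
  if (n_track < params$n_neighbors + 1L) {
    abort(sprintf(
      "series too short: only %d points can be tracked for the %d-sample horizon.",
      max(n_track, 0L), params$horizon
    ))
  }

  nb <- nearest_neighbors(emb, n_track, params)
  ok <- !is.na(nb[, 1L])
  n_skipped <- sum(!ok)
  if (!any(ok)) abort("no reference point admits enough valid neighbours.")
  ri <- rep(which(ok), each = params$n_neighbors)
  nj <- as.integer(t(nb[ok, , drop = FALSE]))
  stopifnot(all(abs(ri - nj) >= params$theiler_window)) # Theiler invariant

  curve <- numeric(params$horizon)
  for (s in seq_len(params$horizon) - 1L) {
    dx <- emb[ri + s, , drop = FALSE] - emb[nj + s, , drop = FALSE]
    d <- sqrt(rowSums(dx^2))
    curve[s + 1L] <- mean(log(pmax(d, params$dist_floor)))
  }

  structure(
    list(
      curve = curve,
      lde = lde_slope(curve, params$fit_range),
      lde_per_stride = lde_slope(curve, params$fit_range) *
        params$samples_per_stride,
      n_pairs_used = length(ri),
      n_skipped = n_skipped,
      pairs = tibble(reference = ri, neighbor = nj),
      params = params
    ),
    class = "lde_result"
  )
}

#' Slope of the log-divergence curve
#'
#' Ordinary least-squares slope of the mean log-divergence curve against the
#' sample index over the first `fit_range` samples.
#'
#' @param curve numeric log-divergence curve.
#' @param fit_range number of leading samples to fit through.
#' @return The slope (ln-units per sample).
#' @export
lde_slope <- function(curve, fit_range) {
  if (fit_range > length(curve)) {
    abort("`fit_range` exceeds the curve length.")
  }
  k <- seq_len(fit_range) - 1
  y <- curve[seq_len(fit_range)]
  sum((k - mean(k)) * (y - mean(y))) / sum((k - mean(k))^2)
}

#' @export
print.lde_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<lde_result> lambda = %.4f per normalized sample ",
      "(%.2f per stride)\n  %d neighbour pairs, %d reference points skipped\n"
    ),
    x$lde, x$lde_per_stride, x$n_pairs_used, x$n_skipped
  ))
  invisible(x)
}

#' @rdname compute_lde
#' @param x an `lde_result`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.lde_result <- function(x, ...) {
  tibble(
    sample = seq_along(x$curve) - 1L,
    log_divergence = x$curve,
    in_fit = seq_along(x$curve) <= x$params$fit_range
  )
}

#' @rdname compute_lde
#' @exportS3Method generics::glance
glance.lde_result <- function(x, ...) {
  tibble(
    lde = x$lde, lde_per_stride = x$lde_per_stride,
    n_pairs_used = x$n_pairs_used, n_skipped = x$n_skipped
  )
}

#' @rdname compute_lde
#' @param object an `lde_result`.
#' @exportS3Method ggplot2::autoplot
autoplot.lde_result <- function(object, ...) {
  d <- tidy.lde_result(object)
  fit0 <- mean(d$log_divergence[d$in_fit]) -
    object$lde * mean(d$sample[d$in_fit])
  ggplot(d, aes(x = .data$sample, y = .data$log_divergence)) +
    geom_line() +
    geom_abline(
      slope = object$lde, intercept = fit0,
      colour = "firebrick", linetype = 2
    ) +
    labs(
      x = "normalized sample",
      y = "mean ln divergence",
      title = sprintf(
        "Local divergence exponent: %.4f / sample (%.2f / stride)",
        object$lde, object$lde_per_stride
      )
    ) +
    theme_minimal()
}
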