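#' Fit the foot placement control model
#'
#' Ordinary least squares of demeaned mediolateral foot placement on the
#' demeaned mediolateral CoM position and velocity at terminal swing:
#' \deqn{FP = \beta_{pos} CoM_{pos} + \beta_{vel} CoM_{vel} + \varepsilon}
#' The relative explained variance R-squared of this fit is the *degree of
#' foot placement control*; the standard deviation of the residual
#' \eqn{\varepsilon} is the *magnitude of foot placement error*.
#'
#' The columns are demeaned (again) inside the fit and an intercept is
#' included: when upstream demeaning is exact the intercept is zero and
#' harmless, and when the demeaning grouping differs from the fit grouping it
#' protects the variance decomposition, making a zero residual mean an
#' invariant rather than an assumption. The residual sd uses the `n - 1`
#' denominator.
#'
#' @param block data frame with columns `fp`, `com_pos`, `com_vel` (m, m,
#'   m/s): one block of a [build_stride_table()] result, or a
#'   [simulate_step_table()] truth table. Rows flagged by `flag_stride_time`
#'   (if present) are dropped first.
#' @return An object of class `fp_fit`: list with `beta_pos`, `beta_vel`,
#'   `r_squared`, `fp_error_sd`, `n_steps`, `n_strides`, `residuals` and the
#'   underlying `lm` fit (`model`).
#' @export
#' @examples
#' truth <- simulate_step_table(synthetic_gait_config(n_strides = 50, seed = 2))
#' fit <- fit_foot_placement_model(truth)
#' glance(fit)
fit_foot_placement_model <- function(block) {
  if (!is.data.frame(block)) abort("`block` must be a data frame.")
  need <- c("fp", "com_pos", "com_vel")
  missing <- setdiff(need, names(block))
  if (length(missing) > 0L) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  if ("flag_stride_time" %in% names(block)) {
    block <- block[!block$flag_stride_time, ]
  }
  n <- nrow(block)
  if (n < 10L) {
    abort(sprintf("at least 10 steps are required to fit the model (got %d).", n))
  }
  d <- tibble(
    fp = block$fp - mean(block$fp),
    com_pos = block$com_pos - mean(block$com_pos),
    com_vel = block$com_vel - mean(block$com_vel)
  )
  if (!all(is.finite(as.matrix(d)))) abort("non-finite values in fit columns.")
  if (sd(d$com_pos) == 0 || sd(d$com_vel) == 0) {
    abort("singular fit: a predictor has zero variance.")
  }
  fit <- lm(fp ~ com_pos + com_vel, data = d)
  res <- resid(fit)
  ss_tot <- sum((d$fp - mean(d$fp))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(res^2) / ss_tot

  structure(
    list(
      beta_pos = unname(coef(fit)["com_pos"]),
      beta_vel = unname(coef(fit)["com_vel"]),
      r_squared = r2,
      fp_error_sd = sd(res),
      n_steps = n,
      n_strides = n / 2,
      residuals = unname(res),
      model = fit
    ),
    class = "fp_fit"
  )
}

#' @export
print.fp_fit <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<fp_fit> %d steps\n  beta_pos = %.3f  beta_vel = %.3f s\n",
      "  R^2 = %.3f  foot placement error sd = %.2f mm\n"
    ),
    x$n_steps, x$beta_pos, x$beta_vel, x$r_squared, 1000 * x$fp_error_sd
  ))
  invisible(x)
}

#' @rdname fit_foot_placement_model
#' @param x an `fp_fit`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.fp_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @rdname fit_foot_placement_model
#' @exportS3Method generics::glance
glance.fp_fit <- function(x, ...) {
  tibble(
    beta_pos = x$beta_pos, beta_vel = x$beta_vel, r_squared = x$r_squared,
    fp_error_sd = x$fp_error_sd, n_steps = x$n_steps, n_strides = x$n_strides
  )
}

#' @rdname fit_foot_placement_model
#' @param object an `fp_fit`.
#' @exportS3Method generics::augment
augment.fp_fit <- function(x, ...) {
  d <- x$model$model
  tibble(
    fp = d$fp, com_pos = d$com_pos, com_vel = d$com_vel,
    .fitted = unname(fitted(x$model)), .resid = x$residuals
  )
}

#' @rdname fit_foot_placement_model
#' @exportS3Method ggplot2::autoplot
autoplot.fp_fit <- function(object, ...) {
  d <- augment.fp_fit(object)
  ggplot(d, aes(x = .data$.fitted, y = .data$fp)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point(alpha = 0.6) +
    labs(
      x = "predicted foot placement (m)",
      y = "observed foot placement (m)",
      title = sprintf(
        "Foot placement control: R² = %.2f, error sd = %.1f mm",
        object$r_squared, 1000 * object$fp_error_sd
      )
    ) +
    theme_minimal()
}

#' Fit the model per block
#'
#' Applies [fit_foot_placement_model()] to every complete block of a stride
#' table and returns one tidy row per block.
#'
#' @param strides a [build_stride_table()] result (or any data frame with
#'   `condition`, `block`, `fp`, `com_pos`, `com_vel`).
#' @return Tibble with columns `condition`, `block`, `beta_pos`, `beta_vel`,
#'   `r_squared`, `fp_error_sd`, `n_steps`, `n_strides`.
#' @export
fit_blocks <- function(strides) {
  strides |>
    filter(!is.na(.data$block)) |>
    group_by(.data$condition, .data$block) |>
    group_modify(~ glance(fit_foot_placement_model(.x))) |>
    ungroup()
}

#' Summarize foot placement fits across blocks
#'
#' Aggregates a list of per-block fits the way within-session outcomes are
#' summarised: `"mean_over_blocks"` takes the unweighted mean of every
#' measure over all blocks; `"first30"` / `"last30"` return the first / last
#' fit in the list (use fits computed on the first and last `block_size`
#' strides of a condition; [analyze_session()] does this).
#'
#' @param fits list of `fp_fit` objects (or a tibble from [fit_blocks()]).
#' @param scheme aggregation scheme.
#' @return A one-row tibble of summary measures plus `n_blocks`.
#' @export
summarize_blocks <- function(fits,
                             scheme = c("mean_over_blocks", "first30", "last30")) {
  scheme <- rlang::arg_match(scheme)
  if (inherits(fits, "fp_fit")) fits <- list(fits)
  tab <- if (is.data.frame(fits)) {
    as_tibble(fits)
  } else {
    if (length(fits) == 0L) abort("`fits` is empty.")
    purrr::map_dfr(fits, glance)
  }
  if (nrow(tab) == 0L) abort("`fits` is empty.")
  measures <- c("beta_pos", "beta_vel", "r_squared", "fp_error_sd")
  picked <- switch(scheme,
    mean_over_blocks = summarise(
      tab,
      across(all_of(measures), mean),
      n_steps = sum(.data$n_steps), n_strides = sum(.data$n_strides)
    ),
    first30 = tab[1L, c(measures, "n_steps", "n_strides")],
    last30 = tab[nrow(tab), c(measures, "n_steps", "n_strides")]
  )
  mutate(picked, n_blocks = nrow(tab), scheme = scheme)
}
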