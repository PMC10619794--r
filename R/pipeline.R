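#' Analyze a full walking session
#'
#' Runs the whole pipeline on one recording: detects heelstrikes, builds the
#' per-step stride table with condition and block labels, fits the foot
#' placement control model per complete block, summarises each condition
#' (mean over blocks, plus dedicated fits on the first and last `block_size`
#' strides), estimates the local divergence exponent of the mediolateral
#' thorax (CoM proxy) velocity per condition, and collects step width and
#' stride time means and exclusion counts.
#'
#' Conditions split across several windows (e.g. three training bouts) are
#' concatenated at the stride level before blocking; a step only belongs to a
#' window when both of its heelstrikes fall inside it, so strides spanning a
#' boundary are dropped. With `lde_scope = "condition"` (default) the
#' divergence exponent is computed once per condition on the concatenation of
#' the per-window time-normalized signals; with `"block"` it is computed per
#' complete block and averaged.
#'
#' @param ts a [marker_series].
#' @param config a [run_config()].
#' @return An object of class `gait_session`: list with `strides` (the
#'   [build_stride_table()] result), `conditions` (named list of per-condition
#'   results: `blocks`, `summary`, `first30`, `last30`, `lde`, `means`,
#'   `counts`), `events`, `config` and `log` (exclusion counts).
#' @export
analyze_session <- function(ts, config = run_config()) {
  stopifnot(inherits(ts, "marker_series"), inherits(config, "run_config"))
  events <- compute_sampling_instants(
    detect_heelstrikes(ts, config$event_params)
  )
  strides <- build_stride_table(ts, events, config)

  p <- default_event_params(config$event_params)
  fs <- sample_rate(ts)
  com_vel_signal <- central_diff(
    lowpass(ts$thorax_ml, fs, p$cutoff), 1 / fs
  )

  plan <- config$condition_plan
  if (is.null(plan)) {
    plan <- tibble(
      condition = "all", start = ts$time[1L],
      end = ts$time[nrow(ts)] + 1
    )
  }
  cond_names <- unique(plan$condition)

  conditions <- lapply(cond_names, function(cn) {
    sub <- filter(strides, .data$condition == cn)
    n_str <- if (nrow(sub) == 0L) 0L else max(sub$stride, na.rm = TRUE)
    counts <- list(
      n_steps = nrow(sub), n_strides = n_str,
      n_flagged = sum(sub$flag_stride_time),
      n_blocks = length(unique(sub$block[!is.na(sub$block)]))
    )
    if (n_str < config$block_size) {
      warn(sprintf(
        "condition '%s' has %d strides (< block_size = %d); summaries are NULL.",
        cn, n_str, config$block_size
      ))
      return(list(
        blocks = NULL, summary = NULL, first30 = NULL, last30 = NULL,
        lde = NULL, means = condition_means(sub), counts = counts
      ))
    }
    blocks <- fit_blocks(sub)
    first30 <- glance(
      fit_foot_placement_model(filter(sub, .data$stride <= config$block_size))
    )
    last30 <- glance(
      fit_foot_placement_model(
        filter(sub, .data$stride > n_str - config$block_size)
      )
    )
    lde <- condition_lde(
      com_vel_signal, ts$time, events, plan[plan$condition == cn, ],
      config, n_str
    )
    list(
      blocks = blocks,
      summary = summarize_blocks(blocks, "mean_over_blocks"),
      first30 = first30, last30 = last30,
      lde = lde, means = condition_means(sub), counts = counts
    )
  })
  names(conditions) <- cond_names

  structure(
    list(
      strides = strides, conditions = conditions, events = events,
      config = config,
      log = list(
        n_events_discarded = events$n_discarded,
        n_steps = nrow(strides),
        n_flagged = sum(strides$flag_stride_time),
        n_unassigned = sum(is.na(strides$condition))
      )
    ),
    class = "gait_session"
  )
}

condition_means <- function(sub) {
  ok <- !sub$flag_stride_time
  list(
    step_width = if (any(ok)) mean(sub$step_width[ok]) else NA_real_,
    stride_time = mean(sub$stride_time[ok], na.rm = TRUE)
  )
}

# one lde_result per condition: per-window normalization, concatenated
condition_lde <- function(signal, time, events, windows, config, n_str) {
  params <- config$lde_params
  segments <- list()
  for (w in seq_len(nrow(windows))) {
    hs <- events$heelstrikes_L
    hs <- hs[hs >= windows$start[w] & hs < windows$end[w]]
    if (length(hs) < 11L) next
    ev <- structure(list(heelstrikes_L = hs), class = "gait_events")
    segments[[length(segments) + 1L]] <-
      as.numeric(time_normalize(signal, time, ev, params))
  }
  if (length(segments) == 0L) {
    warn("no condition window has enough strides for the divergence exponent.")
    return(NULL)
  }
  x <- unlist(segments)
  run_one <- function(y) {
    tryCatch(compute_lde(y, params), error = function(e) {
      warn(sprintf("divergence exponent skipped: %s", conditionMessage(e)))
      NULL
    })
  }
  if (config$lde_scope == "condition") {
    return(run_one(x))
  }
  # per-block: consecutive block_size-stride windows of the normalized signal
  spb <- params$samples_per_stride * config$block_size
  n_blocks <- length(x) %/% spb
  fits <- purrr::compact(lapply(seq_len(n_blocks), function(b) {
    run_one(x[((b - 1L) * spb + 1L):(b * spb)])
  }))
  if (length(fits) == 0L) return(NULL)
  avg <- fits[[1L]]
  avg$curve <- rowMeans(vapply(
    fits, function(f) f$curve, numeric(length(fits[[1L]]$curve))
  ))
  avg$lde <- mean(vapply(fits, function(f) f$lde, numeric(1L)))
  avg$lde_per_stride <- avg$lde * params$samples_per_stride
  avg$n_pairs_used <- sum(vapply(fits, function(f) f$n_pairs_used, numeric(1L)))
  avg$n_skipped <- sum(vapply(fits, function(f) f$n_skipped, numeric(1L)))
  avg
}

#' @export
print.gait_session <- function(x, ...) {
  cat(sprintf(
    "<gait_session> %d steps, %d condition(s): %s\n",
    nrow(x$strides), length(x$conditions),
    paste(names(x$conditions), collapse = ", ")
  ))
  print(tidy(x))
  invisible(x)
}

#' @rdname analyze_session
#' @param x a `gait_session`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.gait_session <- function(x, ...) {
  purrr::imap_dfr(x$conditions, function(res, cn) {
    tibble(
      condition = cn,
      measure = c(
        "r_squared", "fp_error_sd", "step_width", "stride_time", "lde"
      ),
      value = c(
        res$summary$r_squared %||% NA_real_,
        res$summary$fp_error_sd %||% NA_real_,
        res$means$step_width,
        res$means$stride_time,
        if (is.null(res$lde)) NA_real_ else res$lde$lde
      )
    )
  })
}

#' @rdname analyze_session
#' @param object a `gait_session`.
#' @exportS3Method ggplot2::autoplot
autoplot.gait_session <- function(object, ...) {
  blocks <- purrr::imap_dfr(object$conditions, function(res, cn) {
    if (is.null(res$blocks)) return(tibble())
    mutate(res$blocks, condition = cn)
  })
  if (nrow(blocks) == 0L) abort("no complete blocks to plot.")
  long <- tidyr::pivot_longer(
    blocks,
    c("r_squared", "fp_error_sd", "beta_pos", "beta_vel"),
    names_to = "measure", values_to = "value"
  )
  ggplot(long, aes(
    x = .data$block, y = .data$value, colour = .data$condition
  )) +
    geom_line() +
    geom_point() +
    facet_wrap(~measure, scales = "free_y") +
    labs(
      x = "30-stride block", y = NULL,
      title = "Foot placement control per block"
    ) +
    theme_minimal()
}

#' Combine session results into a tidy long table
#'
#' Stacks the condition-level summaries of several sessions into long format
#' (`week`, `session`, `condition`, `measure`, `value`) ready for external
#' repeated-measures statistics. No inferential statistics are computed.
#'
#' @param results list of `gait_session` objects.
#' @param labels data frame with one row per result and columns `week` and
#'   `session`; duplicate (week, session) pairs are an error.
#' @return A tibble in long format.
#' @export
compare_sessions <- function(results, labels) {
  stopifnot(length(results) >= 1L)
  labels <- as_tibble(labels)
  stopifnot(all(c("week", "session") %in% names(labels)))
  if (nrow(labels) != length(results)) {
    abort("`labels` must have one row per result.")
  }
  if (anyDuplicated(labels[, c("week", "session")]) > 0L) {
    abort("duplicate (week, session) labels.")
  }
  purrr::map2_dfr(results, seq_len(nrow(labels)), function(res, i) {
    mutate(
      tidy(res),
      week = labels$week[i], session = labels$session[i],
      .before = 1L
    )
  })
}

#' Write session outputs to a directory
#'
#' Writes the tidy outputs of [analyze_session()]: `strides.csv`,
#' `blocks.csv`, `session_summary.csv`, `lde.json` (divergence curves and
#' exponents) and `run.log` (exclusion counts).
#'
#' @param result a `gait_session`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(result, dir) {
  stopifnot(inherits(result, "gait_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_outcomes(result$strides, file.path(dir, "strides.csv"))
  blocks <- purrr::imap_dfr(result$conditions, function(res, cn) {
    if (is.null(res$blocks)) tibble() else res$blocks
  })
  if (nrow(blocks) > 0L) {
    write_outcomes(blocks, file.path(dir, "blocks.csv"))
  }
  write_outcomes(tidy(result), file.path(dir, "session_summary.csv"))
  lde <- purrr::map(result$conditions, function(res) {
    if (is.null(res$lde)) NULL else {
      list(
        lde = res$lde$lde, lde_per_stride = res$lde$lde_per_stride,
        n_pairs_used = res$lde$n_pairs_used, curve = res$lde$curve
      )
    }
  })
  jsonlite::write_json(
    lde, file.path(dir, "lde.json"), auto_unbox = TRUE, digits = NA,
    null = "null"
  )
  log_lines <- c(
    sprintf("events discarded for alternation: %d", result$log$n_events_discarded),
    sprintf("steps: %d", result$log$n_steps),
    sprintf("steps flagged by stride-time gate: %d", result$log$n_flagged),
    sprintf("steps outside any condition window: %d", result$log$n_unassigned)
  )
  writeLines(log_lines, file.path(dir, "run.log"))
  invisible(dir)
}
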