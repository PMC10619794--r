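#' Run configuration
#'
#' Bundles the settings of a full-session analysis: the condition plan
#' (ordered, non-overlapping, half-open `[start, end)` windows in seconds
#' from recording start), the block size in strides, event-detector
#' parameters and divergence-estimator parameters.
#'
#' @param condition_plan tibble or data frame with columns `condition`,
#'   `start`, `end` (s). `NULL` labels the whole recording as one condition
#'   `"all"`. Multiple windows may share a condition name (e.g. three
#'   training bouts); their strides are concatenated before blocking.
#' @param walking_speed treadmill speed, m/s (informational only).
#' @param block_size strides per analysis block (default 30, minimum 10).
#' @param event_params list passed to [detect_heelstrikes()].
#' @param lde_params an [lde_params()] object.
#' @param lde_scope `"condition"` (default) estimates one divergence exponent
#'   per condition; `"block"` estimates one per 30-stride block and averages.
#' @param seed integer seed for any stochastic step.
#' @return A list of class `run_config`.
#' @export
run_config <- function(condition_plan = NULL,
                       walking_speed = NULL,
                       block_size = 30L,
                       event_params = list(),
                       lde_params = gaitstab::lde_params(),
                       lde_scope = c("condition", "block"),
                       seed = NULL) {
  block_size <- as.integer(block_size)
  if (block_size < 10L) abort("`block_size` must be at least 10 strides.")
  lde_scope <- rlang::arg_match(lde_scope)
  if (!is.null(condition_plan)) {
    condition_plan <- as_tibble(condition_plan)
    stopifnot(all(c("condition", "start", "end") %in% names(condition_plan)))
    if (any(condition_plan$end <= condition_plan$start)) {
      abort("condition windows must have `end` > `start`.")
    }
    cp <- arrange(condition_plan, .data$start)
    if (nrow(cp) > 1L && any(cp$start[-1L] < cp$end[-nrow(cp)])) {
      abort("condition windows must not overlap.")
    }
  }
  structure(
    list(
      condition_plan = condition_plan, walking_speed = walking_speed,
      block_size = block_size, event_params = event_params,
      lde_params = lde_params, lde_scope = lde_scope, seed = seed
    ),
    class = "run_config"
  )
}

interp_at <- function(time, x, at) approx(time, x, xout = at, rule = 2)$y

# central difference, one-sided at the ends
central_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  d[1L] <- (x[2L] - x[1L]) / dt
  d[n] <- (x[n] - x[n - 1L]) / dt
  d
}

demean_by <- function(x, use) {
  m <- mean(x[use])
  if (is.nan(m)) m <- mean(x)
  x - m
}

#' Build the per-step stride table
#'
#' Produces one row per step with everything the foot placement control model
#' needs:
#'
#' * `step_width` — absolute mediolateral distance between the heel markers
#'   at midstance, m;
#' * `fp` — foot placement: signed mediolateral position of the new stance
#'   heel relative to the previous stance heel at midstance, mirrored for
#'   left steps so that wider-than-usual placement is positive, then demeaned
#'   per block and side;
#' * `com_pos`, `com_vel` — mediolateral thorax (CoM proxy) position relative
#'   to the stance heel and its velocity, both at terminal swing,
#'   mirrored and demeaned the same way;
#' * `stride_time` — time between two successive same-side heelstrikes, s;
#' * `condition`, `stride`, `block` — labels from the condition plan; a step
#'   belongs to a condition only if both of its defining heelstrikes fall in
#'   the window; strides are pairs of consecutive steps and blocks are
#'   `block_size` complete strides (incomplete trailing blocks stay
#'   unassigned).
#'
#' All signals are low-pass filtered ([lowpass()]) before interpolation and
#' differentiation. Steps whose stride time falls outside \[0.4, 3\] s are
#' flagged (`flag_stride_time`) and excluded from demeaning and model fits.
#'
#' @param ts a [marker_series].
#' @param events a `gait_events` object; sampling instants are derived with
#'   [compute_sampling_instants()] if missing.
#' @param config a [run_config()].
#' @return A tibble of class `stride_table`.
#' @export
build_stride_table <- function(ts, events, config = run_config()) {
  stopifnot(inherits(ts, "marker_series"), inherits(events, "gait_events"))
  if (!"midstance" %in% names(events$steps)) {
    events <- compute_sampling_instants(events)
  }
  p <- default_event_params(config$event_params)
  fs <- sample_rate(ts)
  time <- ts$time
  sm <- lapply(
    list(
      heel_L = ts$heel_L_ml, heel_R = ts$heel_R_ml, thorax = ts$thorax_ml
    ),
    lowpass, sample_rate = fs, cutoff = p$cutoff
  )
  thorax_vel <- central_diff(sm$thorax, 1 / fs)

  steps <- events$steps
  n <- nrow(steps)
  if (n < 2L) abort("insufficient gait: fewer than 2 steps with instants.")
  out <- steps[-1L, c("side", "t_hs", "terminal_swing", "midstance")]
  prev_hs <- steps$t_hs[-n]
  contra <- ifelse(out$side == "L", "heel_R", "heel_L")
  own <- ifelse(out$side == "L", "heel_L", "heel_R")

  heel_at_mid <- vapply(seq_len(nrow(out)), function(i) {
    c(
      interp_at(time, sm[[own[i]]], out$midstance[i]),
      interp_at(time, sm[[contra[i]]], out$midstance[i]),
      interp_at(time, sm[[contra[i]]], out$terminal_swing[i])
    )
  }, numeric(3L))

  mirror <- ifelse(out$side == "R", 1, -1)
  out$step_width <- abs(heel_at_mid[1L, ] - heel_at_mid[2L, ])
  fp_raw <- heel_at_mid[1L, ] - heel_at_mid[2L, ]
  com_pos_raw <- interp_at(time, sm$thorax, out$terminal_swing) -
    heel_at_mid[3L, ]
  com_vel_raw <- interp_at(time, thorax_vel, out$terminal_swing)

  same_side_prev <- c(NA_real_, NA_real_, out$t_hs[seq_len(nrow(out) - 2L)])
  out$stride_time <- out$t_hs - same_side_prev
  out$flag_stride_time <- !is.na(out$stride_time) &
    (out$stride_time < 0.4 | out$stride_time > 3)

  # condition label: both defining heelstrikes inside the half-open window
  plan <- config$condition_plan
  if (is.null(plan)) {
    plan <- tibble(
      condition = "all", start = time[1L], end = time[length(time)] + 1
    )
  }
  cond <- rep(NA_character_, nrow(out))
  for (w in seq_len(nrow(plan))) {
    hit <- prev_hs >= plan$start[w] & out$t_hs < plan$end[w] &
      prev_hs < plan$end[w] & out$t_hs >= plan$start[w]
    cond[hit] <- plan$condition[w]
  }
  out$condition <- cond

  # stride and block numbering within condition (time order)
  out <- out |>
    group_by(.data$condition) |>
    mutate(
      stride = ifelse(is.na(.data$condition), NA_integer_,
        as.integer(ceiling(row_number() / 2))
      ),
      block = {
        b <- (.data$stride - 1L) %/% config$block_size + 1L
        n_strides <- ifelse(is.na(.data$condition), 0L,
          max(.data$stride, 0L, na.rm = TRUE)
        )
        complete <- n_strides %/% config$block_size
        ifelse(!is.na(b) & b <= complete, as.integer(b), NA_integer_)
      }
    ) |>
    ungroup()

  out$fp_raw <- fp_raw
  out$com_pos_raw <- com_pos_raw
  out$com_vel_raw <- com_vel_raw

  # demean per (condition, block, side) over unflagged rows, then mirror
  grp_block <- ifelse(is.na(out$block), -1L, out$block)
  out <- out |>
    mutate(.grp_block = grp_block, .mirror = mirror) |>
    group_by(.data$condition, .data$.grp_block, .data$side) |>
    mutate(
      fp = .data$.mirror * demean_by(.data$fp_raw, !.data$flag_stride_time),
      com_pos = .data$.mirror *
        demean_by(.data$com_pos_raw, !.data$flag_stride_time),
      com_vel = .data$.mirror *
        demean_by(.data$com_vel_raw, !.data$flag_stride_time)
    ) |>
    ungroup() |>
    select(-".grp_block", -".mirror")

  out <- out |>
    mutate(step = row_number(), .before = 1L) |>
    select(
      "step", "side", "t_hs", "terminal_swing", "midstance", "condition",
      "stride", "block", "step_width", "stride_time", "fp", "com_pos",
      "com_vel", "fp_raw", "com_pos_raw", "com_vel_raw", "flag_stride_time"
    )
  class(out) <- c("stride_table", class(out))
  out
}
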