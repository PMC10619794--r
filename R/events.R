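#' Zero-phase low-pass filter
#'
#' Bidirectional (zero-lag) Butterworth low-pass, applied forwards and
#' backwards (effective 4th order for the default 2nd-order design). All
#' marker signals are filtered with this before differentiation or event
#' detection.
#'
#' @param x numeric signal.
#' @param sample_rate sampling rate, Hz.
#' @param cutoff cutoff frequency, Hz (default 10, preserving gait content at
#'   typical 100 Hz sampling).
#' @param order filter order of the one-way design.
#' @return Filtered numeric vector of the same length.
#' @export
lowpass <- function(x, sample_rate, cutoff = 10, order = 2L) {
  if (cutoff <= 0 || cutoff >= sample_rate / 2) {
    abort("`cutoff` must lie in (0, Nyquist).")
  }
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

default_event_params <- function(params = list()) {
  defaults <- list(cutoff = 10, min_spacing = 0.4, edge_margin = 0.5)
  utils::modifyList(defaults, params)
}

# strict-rise local maxima, min-spacing enforced by keeping the taller peak
find_peaks <- function(x, min_gap) {
  n <- length(x)
  if (n < 3L) return(integer())
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (length(cand) == 0L) return(integer())
  keep <- logical(length(cand))
  for (o in order(-x[cand])) {
    if (!any(keep & abs(cand - cand[o]) < min_gap)) keep[o] <- TRUE
  }
  sort(cand[keep])
}

#' Detect heelstrikes from heel kinematics
#'
#' Kinematic treadmill-frame event detection: a heelstrike is a local maximum
#' of the heel's anteroposterior position relative to the thorax. Candidate
#' maxima closer than `min_spacing` (s) on the same side are resolved in
#' favour of the larger excursion; events within `edge_margin` (s) of the
#' record edges are dropped; left/right alternation is enforced by discarding
#' the weaker of two consecutive same-side events (a warning reports how many
#' were discarded).
#'
#' @param ts a [marker_series] with markers `heel_L`, `heel_R`, `thorax` and
#'   at least 5 s of data.
#' @param params optional list overriding `cutoff` (Hz), `min_spacing` (s),
#'   `edge_margin` (s).
#' @return A `gait_events` object: list with `heelstrikes_L`,
#'   `heelstrikes_R` (times, s), `steps` (tibble of merged alternating
#'   events) and `n_discarded`.
#' @export
detect_heelstrikes <- function(ts, params = list()) {
  stopifnot(inherits(ts, "marker_series"))
  check_required_markers(names(ts))
  p <- default_event_params(params)
  fs <- sample_rate(ts)
  time <- ts$time
  if (time[length(time)] - time[1L] < 5) {
    abort("at least 5 s of data are required for event detection.")
  }
  gap <- round(p$min_spacing * fs)

  events <- lapply(c(L = "L", R = "R"), function(side) {
    rel <- lowpass(ts[[paste0("heel_", side, "_ap")]], fs, p$cutoff) -
      lowpass(ts$thorax_ap, fs, p$cutoff)
    idx <- find_peaks(rel, gap)
    t_ev <- time[idx]
    inside <- t_ev >= time[1L] + p$edge_margin &
      t_ev <= time[length(time)] - p$edge_margin
    list(time = t_ev[inside], height = rel[idx][inside])
  })
  for (side in c("L", "R")) {
    if (length(events[[side]]$time) < 3L) {
      abort(sprintf(
        "insufficient gait: only %d heelstrikes detected on side %s.",
        length(events[[side]]$time), side
      ))
    }
  }

  merged <- tibble(
    side = rep(c("L", "R"), c(length(events$L$time), length(events$R$time))),
    t_hs = c(events$L$time, events$R$time),
    height = c(events$L$height, events$R$height)
  ) |>
    arrange(.data$t_hs)

  # enforce alternation: of two consecutive same-side events keep the taller
  n_discarded <- 0L
  repeat {
    same <- which(merged$side[-1L] == merged$side[-nrow(merged)])
    if (length(same) == 0L) break
    i <- same[1L]
    drop <- if (merged$height[i] >= merged$height[i + 1L]) i + 1L else i
    merged <- merged[-drop, ]
    n_discarded <- n_discarded + 1L
  }
  if (n_discarded > 0L) {
    warn(sprintf(
      "non-alternating heelstrikes: discarded %d weaker candidate(s).",
      n_discarded
    ))
  }

  structure(
    list(
      heelstrikes_L = merged$t_hs[merged$side == "L"],
      heelstrikes_R = merged$t_hs[merged$side == "R"],
      steps = select(merged, "side", "t_hs"),
      n_discarded = n_discarded
    ),
    class = "gait_events"
  )
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf(
    "<gait_events> %d left / %d right heelstrikes over %.1f s\n",
    length(x$heelstrikes_L), length(x$heelstrikes_R),
    diff(range(x$steps$t_hs))
  ))
  invisible(x)
}

#' Derive midstance and terminal-swing sampling instants
#'
#' For a step ending with the heelstrike of foot F at time `t_hs`, the
#' terminal-swing instant (at which the CoM predictors are sampled) is
#' `t_hs` itself, offset backwards by `offset` seconds if requested, and the
#' midstance of the new stance phase is the temporal midpoint between `t_hs`
#' and the next contralateral heelstrike. The final step, which lacks a
#' following contralateral event, is dropped.
#'
#' @param events a `gait_events` object from [detect_heelstrikes()].
#' @param offset terminal-swing offset, s before heelstrike (default 0).
#' @return The `gait_events` object with `steps` gaining `terminal_swing`
#'   and `midstance` columns.
#' @export
compute_sampling_instants <- function(events, offset = 0) {
  stopifnot(inherits(events, "gait_events"))
  steps <- events$steps
  n <- nrow(steps)
  nxt <- c(steps$t_hs[-1L], NA_real_)
  steps$terminal_swing <- steps$t_hs - offset
  steps$midstance <- (steps$t_hs + nxt) / 2
  events$steps <- steps[!is.na(steps$midstance), ]
  events
}
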