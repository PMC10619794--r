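#' Synthetic gait configuration
#'
#' Parameters of the synthetic treadmill-walking generator. The generator
#' draws a per-step center-of-mass (CoM) state and applies the foot placement
#' control model
#' \deqn{FP = \beta_{pos} CoM_{pos} + \beta_{vel} CoM_{vel} + \varepsilon}
#' so that every downstream estimate (regression coefficients, R-squared,
#' residual sd, step width, stride time, heelstrike times) has a known ground
#' truth.
#'
#' All step-wise quantities are expressed in the side-invariant "analysis
#' frame": left steps are mirrored so that a positive foot placement deviation
#' always means a wider-than-usual lateral placement.
#'
#' @param n_strides number of strides to simulate (>= 35; one stride is a
#'   left plus a right step).
#' @param stride_time_mean,stride_time_sd mean and sd of stride time, s.
#' @param step_width_mean mean step width, m.
#' @param com_sway_sd sd of the mediolateral CoM position at terminal swing
#'   relative to the stance foot, m.
#' @param com_vel_sd sd of the mediolateral CoM velocity at terminal swing,
#'   m/s.
#' @param beta_pos,beta_vel foot placement control gains on CoM position
#'   (dimensionless) and velocity (s).
#' @param sigma_eps sd of the foot placement error (model residual), m.
#' @param sample_rate rendering sample rate, Hz.
#' @param com_phi lag-1 autocorrelation of the per-step CoM position draws.
#'   The default 0 gives i.i.d. draws, which keeps ordinary-least-squares
#'   recovery bounds analytic; a positive value gives AR(1) sway with the
#'   same marginal sd, useful for divergence-exponent sensitivity checks.
#' @param step_length AP excursion of a heel over one step in the treadmill
#'   frame, m (rendering only).
#' @param swing_lift peak vertical heel lift during swing, m (rendering only).
#' @param seed integer seed making all draws reproducible; `NULL` uses the
#'   current RNG state.
#'
#' @return A list of class `synthetic_gait_config`.
#' @export
synthetic_gait_config <- function(n_strides = 300L,
                                  stride_time_mean = 1.1,
                                  stride_time_sd = 0.02,
                                  step_width_mean = 0.10,
                                  com_sway_sd = 0.01,
                                  com_vel_sd = 0.05,
                                  beta_pos = 1.5,
                                  beta_vel = 0.30,
                                  sigma_eps = 0.005,
                                  sample_rate = 100,
                                  com_phi = 0,
                                  step_length = 0.60,
                                  swing_lift = 0.05,
                                  seed = NULL) {
  cfg <- list(
    n_strides = as.integer(n_strides), stride_time_mean = stride_time_mean,
    stride_time_sd = stride_time_sd, step_width_mean = step_width_mean,
    com_sway_sd = com_sway_sd, com_vel_sd = com_vel_sd,
    beta_pos = beta_pos, beta_vel = beta_vel, sigma_eps = sigma_eps,
    sample_rate = sample_rate, com_phi = com_phi,
    step_length = step_length, swing_lift = swing_lift, seed = seed
  )
  scales <- c(
    "stride_time_mean", "step_width_mean", "sample_rate", "step_length"
  )
  for (f in scales) {
    if (cfg[[f]] <= 0) abort(sprintf("`%s` must be positive.", f))
  }
  nonneg <- c(
    "stride_time_sd", "com_sway_sd", "com_vel_sd", "sigma_eps", "swing_lift"
  )
  for (f in nonneg) {
    if (cfg[[f]] < 0) abort(sprintf("`%s` must be non-negative.", f))
  }
  if (cfg$n_strides < 35L) {
    abort("`n_strides` must be at least 35 for any block analysis.")
  }
  if (cfg$com_phi < 0 || cfg$com_phi >= 1) {
    abort("`com_phi` must be in [0, 1).")
  }
  class(cfg) <- "synthetic_gait_config"
  cfg
}

with_config_seed <- function(config, code) {
  if (is.null(config$seed)) force(code) else withr::with_seed(config$seed, code)
}

#' Simulate a step truth table
#'
#' Draws the per-step ground truth of the synthetic walker: alternating
#' left/right steps with heelstrike times, CoM state at terminal swing, foot
#' placement error and realized step width. The foot placement deviation
#' satisfies `fp = beta_pos * com_pos + beta_vel * com_vel + eps` exactly, by
#' construction, in the side-invariant analysis frame.
#'
#' Step durations are drawn as independent half-stride normals (mean
#' `stride_time_mean / 2`, sd `stride_time_sd / sqrt(2)`, truncated at a
#' quarter of the mean stride time) so that same-leg stride times are
#' `Normal(stride_time_mean, stride_time_sd)` truncated at half the mean.
#'
#' @param config a [synthetic_gait_config()].
#' @return A tibble of class `step_truth` with `2 * n_strides` rows and
#'   columns `step`, `stride`, `side`, `t_hs` (heelstrike time, s),
#'   `com_pos` (m), `com_vel` (m/s), `eps` (m), `fp` (m), `step_width` (m),
#'   `stride_time` (s).
#' @export
#' @examples
#' truth <- simulate_step_table(synthetic_gait_config(n_strides = 40, seed = 1))
#' head(truth)
simulate_step_table <- function(config) {
  stopifnot(inherits(config, "synthetic_gait_config"))
  n_steps <- 2L * config$n_strides
  with_config_seed(config, {
    half_mean <- config$stride_time_mean / 2
    half_sd <- config$stride_time_sd / sqrt(2)
    dur <- rnorm(n_steps + 1L, half_mean, half_sd)
    dur <- pmax(dur, config$stride_time_mean / 4)

    com_pos <- rnorm(n_steps, 0, config$com_sway_sd)
    if (config$com_phi > 0) {
      # AR(1) with the same marginal sd: innovations scaled by sqrt(1 - phi^2)
      phi <- config$com_phi
      innov <- com_pos * sqrt(1 - phi^2)
      innov[1L] <- com_pos[1L]
      com_pos <- as.numeric(stats::filter(innov, phi, method = "recursive"))
    }
    com_vel <- rnorm(n_steps, 0, config$com_vel_sd)
    eps <- rnorm(n_steps, 0, config$sigma_eps)
    fp <- config$beta_pos * com_pos + config$beta_vel * com_vel + eps

    # lead-in stance starts inside the detector's edge margin so the virtual
    # step-0 contact never counts as an event; the first real heelstrike
    # lands ~1 s into the record
    t0 <- 0.45
    t_hs <- t0 + cumsum(dur[-1L])
    side <- rep_len(c("L", "R"), n_steps)
    stride_time <- c(NA_real_, NA_real_, diff(t_hs, lag = 2L))

    tibble(
      step = seq_len(n_steps),
      stride = ceiling(seq_len(n_steps) / 2),
      side = side,
      t_hs = t_hs,
      com_pos = com_pos,
      com_vel = com_vel,
      eps = eps,
      fp = fp,
      step_width = config$step_width_mean + fp,
      stride_time = stride_time
    ) |>
      structure(
        class = c("step_truth", class(tibble())),
        t_first_stance = t0,
        config = config
      )
  })
}

# C1 smoothstep, 0 at u<=0, 1 at u>=1
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Render a truth table as continuous marker trajectories
#'
#' Turns a [simulate_step_table()] truth table into continuous heel and
#' thorax marker trajectories sampled at `sample_rate`, so that event
#' detection and the marker-level pipeline can be validated against ground
#' truth.
#'
#' Heel trajectories in the treadmill frame: during stance the heel moves
#' backwards linearly in AP and holds its lateral placement; during swing the
#' AP coordinate returns forward linearly (making the relative AP signal a
#' symmetric triangle wave whose apex marks the contact), the vertical
#' coordinate follows a half-sine lift, and the lateral coordinate moves to
#' the next placement along a C1 smoothstep confined to the second half of
#' swing (so at the contralateral midstance the trailing heel still marks its
#' previous placement). The thorax mediolateral trajectory is a cubic Hermite
#' spline through each step's CoM position (relative to the stance heel,
#' converted to the lab frame) with the drawn CoM velocity as knot slope, so
#' both position and velocity ground truth are recoverable at terminal swing.
#'
#' Ground-truth heelstrike times are stored in the metadata as
#' `truth_heelstrikes_L` / `truth_heelstrikes_R`.
#'
#' @param truth a `step_truth` table from [simulate_step_table()].
#' @param config the [synthetic_gait_config()] used to create it.
#' @return A [marker_series].
#' @export
render_continuous <- function(truth, config) {
  stopifnot(inherits(truth, "step_truth"), nrow(truth) > 0L)
  n_steps <- nrow(truth)
  t0 <- attr(truth, "t_first_stance")

  # lab-frame lateral landing positions: the foot landing at step k is placed
  # step_width away from the current stance foot, to the landing side
  sgn <- ifelse(truth$side == "R", 1, -1)
  q <- numeric(n_steps + 1L) # q[1] = initial stance foot (virtual step 0)
  q[1L] <- 0
  for (k in seq_len(n_steps)) q[k + 1L] <- q[k] + sgn[k] * truth$step_width[k]
  t_land <- c(t0, truth$t_hs) # landing time of q[k]

  duration <- truth$t_hs[n_steps] + 0.6
  time <- seq(0, duration, by = 1 / config$sample_rate)
  ns <- length(time)

  heel <- list(
    L = list(ml = numeric(ns), ap = numeric(ns), vert = numeric(ns)),
    R = list(ml = numeric(ns), ap = numeric(ns), vert = numeric(ns))
  )
  side0 <- if (truth$side[1L] == "L") "R" else "L" # virtual step 0 side
  step_side <- c(side0, truth$side)
  amp <- config$step_length / 2

  for (s in c("L", "R")) {
    own <- which(step_side == s) # indices into q / t_land
    ml <- rep(q[own[1L]], ns)
    ap <- rep(amp, ns)
    vert <- numeric(ns)
    # incoming swing into the foot's first landing, so the first contact is a
    # genuine AP maximum rather than a plateau edge
    k1 <- own[1L]
    t_first <- t_land[k1]
    t_pre <- if (k1 > 1L) t_land[k1 - 1L] else t_first - config$stride_time_mean / 2
    pre <- time < t_first
    u0 <- pmin(pmax((time[pre] - t_pre) / (t_first - t_pre), 0), 1)
    ap[pre] <- -amp + 2 * amp * u0
    vert[pre] <- config$swing_lift * sin(pi * u0)
    for (idx in seq_along(own)) {
      k <- own[idx]
      t_on <- t_land[k]
      # stance until the contralateral landing (or record end)
      t_off <- if (k + 1L <= length(t_land)) t_land[k + 1L] else duration
      in_st <- time >= t_on & time < t_off
      ml[time >= t_on] <- q[k]
      ap[in_st] <- amp - 2 * amp * (time[in_st] - t_on) / (t_off - t_on)
      vert[in_st] <- 0
      ap[time >= t_off] <- -amp
      # swing from t_off to own next landing
      if (idx < length(own)) {
        t_next <- t_land[own[idx + 1L]]
        in_sw <- time >= t_off & time < t_next
        u <- (time[in_sw] - t_off) / (t_next - t_off)
        ap[in_sw] <- -amp + 2 * amp * u
        vert[in_sw] <- config$swing_lift * sin(pi * u)
        ml[in_sw] <- q[k] +
          (q[own[idx + 1L]] - q[k]) * smoothstep((u - 0.5) / 0.5)
      }
    }
    heel[[s]] <- list(ml = ml, ap = ap, vert = vert)
  }

  # thorax ML: Hermite spline through lab-frame CoM positions at terminal
  # swing (the heelstrike instants), with matching lab-frame velocities
  knot_t <- c(t0, truth$t_hs)
  knot_y <- c(q[1L], q[seq_len(n_steps)] + sgn * truth$com_pos)
  knot_m <- c(0, sgn * truth$com_vel)
  thorax_ml <- splinefunH(knot_t, knot_y, knot_m)(time)

  ts <- tibble(
    time = time,
    heel_L_ml = heel$L$ml, heel_L_ap = heel$L$ap, heel_L_vert = heel$L$vert,
    heel_R_ml = heel$R$ml, heel_R_ap = heel$R$ap, heel_R_vert = heel$R$vert,
    thorax_ml = thorax_ml, thorax_ap = 0, thorax_vert = 1
  )
  marker_series(
    ts,
    sample_rate = config$sample_rate,
    metadata = list(
      synthetic = TRUE,
      truth_heelstrikes_L = truth$t_hs[truth$side == "L"],
      truth_heelstrikes_R = truth$t_hs[truth$side == "R"]
    )
  )
}

#' Simulate reference time series for divergence calibration
#'
#' Generates scalar series with known dynamical properties, used to calibrate
#' and test the local divergence exponent estimator:
#'
#' * `"periodic"` — sum of two harmonics of a base period; exactly periodic.
#' * `"logistic_map"` — iterates of `x <- r x (1 - x)`; at `r = 4` the
#'   largest Lyapunov exponent is `ln 2` per iterate.
#' * `"noisy_limit_cycle"` — the periodic signal with per-cycle amplitude and
#'   phase jitter; `jitter_sd = 0` reduces it to `"periodic"` exactly.
#'
#' @param kind one of `"periodic"`, `"logistic_map"`, `"noisy_limit_cycle"`.
#' @param n_samples series length (>= 2000 for the logistic map).
#' @param period samples per cycle for the periodic kinds.
#' @param r,x0 logistic map rate and initial state.
#' @param jitter_sd per-cycle jitter sd: amplitude as a fraction of 1,
#'   phase as a fraction of one cycle.
#' @param seed integer seed (used by the jittered kind).
#' @return A numeric vector of length `n_samples`.
#' @export
simulate_reference_series <- function(kind = c("periodic", "logistic_map",
                                               "noisy_limit_cycle"),
                                      n_samples,
                                      period = 100L,
                                      r = 4,
                                      x0 = 0.3,
                                      jitter_sd = 0.05,
                                      seed = NULL) {
  kind <- rlang::arg_match(kind)
  n_samples <- as.integer(n_samples)
  if (n_samples < 2L) abort("`n_samples` must be at least 2.")
  two_harmonics <- function(phase, amp) {
    amp * (sin(2 * pi * phase) + 0.5 * sin(4 * pi * phase))
  }
  switch(kind,
    periodic = two_harmonics((seq_len(n_samples) - 1) / period, 1),
    logistic_map = {
      if (n_samples < 2000L) {
        abort("`n_samples` must be >= 2000 for the logistic map.")
      }
      x <- numeric(n_samples)
      x[1L] <- x0
      for (i in seq_len(n_samples - 1L)) x[i + 1L] <- r * x[i] * (1 - x[i])
      x
    },
    noisy_limit_cycle = {
      run <- function() {
        n_cycles <- ceiling(n_samples / period)
        amp <- 1 + rnorm(n_cycles, 0, jitter_sd)
        ph <- rnorm(n_cycles, 0, jitter_sd)
        i <- seq_len(n_samples) - 1
        cyc <- i %/% period + 1L
        two_harmonics(i / period + ph[cyc], amp[cyc])
      }
      if (is.null(seed)) run() else withr::with_seed(seed, run())
    }
  )
}
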