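#' Marker time series
#'
#' A `marker_series` is a tibble with a `time` column (seconds, strictly
#' increasing, uniformly sampled) and one column per marker coordinate, named
#' `<marker>_<axis>` with axis one of `ml` (mediolateral, positive to the
#' participant's right), `ap` (anteroposterior, positive in the walking
#' direction) or `vert` (vertical, positive up). Positions are in meters.
#' The analysis functions require the markers `heel_L`, `heel_R` and `thorax`
#' (the latter serving as center-of-mass proxy).
#'
#' The sampling rate (Hz) is stored in the `sample_rate` attribute and
#' free-form metadata (subject id, condition, ground-truth event times for
#' synthetic data, ...) in the `metadata` attribute.
#'
#' @param data data frame with a `time` column and marker coordinate columns.
#' @param sample_rate sampling rate in Hz; inferred from `time` when `NULL`.
#' @param metadata named list of free-form metadata.
#'
#' @return A tibble of class `marker_series`.
#' @export
#' @examples
#' ts <- marker_series(tibble::tibble(
#'   time = seq(0, 0.05, by = 0.01),
#'   heel_L_ml = -0.05, heel_L_ap = 0, heel_L_vert = 0,
#'   heel_R_ml = 0.05, heel_R_ap = 0, heel_R_vert = 0,
#'   thorax_ml = 0, thorax_ap = 0, thorax_vert = 1
#' ))
#' sample_rate(ts)
marker_series <- function(data, sample_rate = NULL, metadata = list()) {
  data <- as_tibble(data)
  if (!"time" %in% names(data)) {
    abort("`data` must contain a `time` column.")
  }
  time <- data$time
  if (length(time) < 2L) {
    abort("`data` must contain at least two samples.")
  }
  dt <- diff(time)
  if (any(dt <= 0)) {
    abort("`time` must be strictly increasing.")
  }
  step <- stats::median(dt)
  dev <- max(abs(dt - step))
  if (dev > 1e-6) {
    abort(sprintf(
      "`time` must be uniformly sampled; maximum spacing deviation is %.3g s.",
      dev
    ))
  }
  if (is.null(sample_rate)) sample_rate <- 1 / step
  if (abs(1 / sample_rate - step) > 1e-6) {
    abort(sprintf(
      "`sample_rate` (%g Hz) is inconsistent with the time vector spacing (%g s).",
      sample_rate, step
    ))
  }
  structure(
    data,
    sample_rate = sample_rate,
    metadata = metadata,
    class = c("marker_series", class(data))
  )
}

#' @rdname marker_series
#' @param x a `marker_series`.
#' @export
sample_rate <- function(x) attr(x, "sample_rate")

#' @rdname marker_series
#' @export
series_metadata <- function(x) attr(x, "metadata")

required_markers <- c("heel_L", "heel_R", "thorax")
marker_axes <- c("ml", "ap", "vert")

marker_columns <- function(markers) {
  as.vector(t(outer(markers, marker_axes, paste, sep = "_")))
}

check_required_markers <- function(cols) {
  for (m in required_markers) {
    missing <- setdiff(paste(m, marker_axes, sep = "_"), cols)
    if (length(missing) > 0L) {
      abort(sprintf("missing marker %s (column %s)", m, missing[1L]))
    }
  }
  invisible(TRUE)
}

#' Read marker trajectories from CSV
#'
#' Reads the normative plain-CSV dialect: comma separated, `.` decimal, a
#' header row `time,heel_L_ml,heel_L_ap,heel_L_vert,...`, one row per sample,
#' time in seconds and positions in meters. The markers `heel_L`, `heel_R`
#' and `thorax` are required; additional columns are preserved and listed in
#' the metadata under `extra_columns`.
#'
#' C3D motion-capture files are not read directly; export the heel and trunk
#' trajectories to this CSV dialect first.
#'
#' @param path path to a CSV file.
#' @return A [marker_series].
#' @export
read_marker_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"time" %in% names(data)) abort("missing `time` column")
  check_required_markers(names(data))
  extra <- setdiff(names(data), c("time", marker_columns(required_markers)))
  meta <- list(source = path)
  if (length(extra) > 0L) meta$extra_columns <- extra
  marker_series(data, metadata = meta)
}

#' Write marker trajectories to CSV
#'
#' Writes the normative CSV dialect read by [read_marker_csv()]. Values
#' round-trip losslessly (to well below 1e-9 m).
#'
#' @param ts a [marker_series].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_csv <- function(ts, path) {
  readr::write_csv(as_tibble(as.data.frame(ts)), path, progress = FALSE)
  invisible(path)
}

#' Write a tidy outcome table to CSV
#'
#' Writes a stride table, block-fit table or session summary as tidy CSV, one
#' row per stride or block. Re-reading with [read_outcomes()] reproduces all
#' numeric values to better than 1e-9.
#'
#' @param table a non-empty data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(table, path) {
  if (!is.data.frame(table)) abort("`table` must be a data frame.")
  if (nrow(table) == 0L) abort("`table` is empty; nothing written.")
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_outcomes
#' @export
read_outcomes <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a run configuration file
#'
#' Reads a flat YAML file mirroring the fields of [run_config()]:
#' `walking_speed`, `block_size`, `seed`, an optional `event_params` /
#' `lde_params` mapping and a `condition_plan` list of
#' `{condition, start, end}` entries (seconds, half-open windows).
#'
#' @param path path to a YAML configuration file.
#' @return A [run_config] object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- yaml::read_yaml(path)
  plan <- NULL
  if (!is.null(raw$condition_plan)) {
    plan <- purrr::map_dfr(raw$condition_plan, ~ tibble(
      condition = .x$condition, start = as.numeric(.x$start),
      end = as.numeric(.x$end)
    ))
  }
  run_config(
    condition_plan = plan,
    walking_speed = raw$walking_speed %||% NULL,
    block_size = raw$block_size %||% 30L,
    event_params = raw$event_params %||% list(),
    lde_params = do.call(lde_params, raw$lde_params %||% list()),
    seed = raw$seed %||% NULL
  )
}
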