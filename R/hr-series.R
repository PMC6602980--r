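#' Raw (possibly non-uniform) heart-rate samples
#'
#' Container for a heart-rate stream as it comes off a monitor export:
#' timestamped samples that need not be uniformly spaced. All analysis
#' functions operate on the uniformly resampled [hr_series()]; raw samples
#' are the input to [resample_uniform()].
#'
#' @param times Numeric vector of sample times in seconds from recording
#'   start; strictly increasing, non-negative.
#' @param values Numeric vector of heart rate in beats per minute (bpm);
#'   finite and strictly positive, same length as `times`.
#' @param source_label Free-text provenance label (e.g. a file path).
#'
#' @return An object of class `hr_samples` with fields `times`, `values`,
#'   `source_label`.
#' @seealso [resample_uniform()], [read_hr_csv()]
#' @export
#' @examples
#' hr_samples(c(0, 1, 2), c(60, 61, 62))
hr_samples <- function(times, values, source_label = "") {
  if (!is.numeric(times) || !is.numeric(values)) {
    hrv_validation_error("`times` and `values` must be numeric")
  }
  if (length(times) != length(values)) {
    hrv_validation_error("`times` and `values` must have the same length")
  }
  if (anyNA(times) || any(!is.finite(times))) {
    hrv_validation_error("sample times must be finite")
  }
  if (length(times) > 0 && times[1] < 0) {
    hrv_validation_error("sample times must be non-negative")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    hrv_validation_error("sample times must be strictly increasing")
  }
  if (anyNA(values) || any(!is.finite(values)) || any(values <= 0)) {
    hrv_validation_error("heart-rate values must be finite and > 0 bpm")
  }
  structure(
    list(times = as.numeric(times), values = as.numeric(values),
         source_label = as.character(source_label)[1]),
    class = "hr_samples"
  )
}

#' @export
print.hr_samples <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<hr_samples> %d samples", n))
  if (n > 0) {
    cat(sprintf(", t = [%.3f, %.3f] s, HR = [%.1f, %.1f] bpm",
                x$times[1], x$times[n], min(x$values), max(x$values)))
  }
  if (nzchar(x$source_label)) cat(sprintf("\n  source: %s", x$source_label))
  cat("\n")
  invisible(x)
}

#' Ordered beat-annotation times
#'
#' Beat occurrence times (seconds from recording start), e.g. parsed from a
#' beat-annotation file. Instantaneous heart rate is derived from them with
#' [beats_to_instantaneous_hr()].
#'
#' @param beat_times Strictly increasing numeric vector of beat times in
#'   seconds.
#' @param labels Optional character vector of per-beat annotation symbols
#'   (e.g. `"N"` for a normal beat), same length as `beat_times`.
#'
#' @return An object of class `beat_series`.
#' @seealso [read_beat_annotations()], [beats_to_instantaneous_hr()]
#' @export
beat_series <- function(beat_times, labels = NULL) {
  if (!is.numeric(beat_times) || anyNA(beat_times) || any(!is.finite(beat_times))) {
    hrv_validation_error("beat times must be finite numbers")
  }
  if (length(beat_times) > 1 && any(diff(beat_times) <= 0)) {
    hrv_validation_error("beat times must be strictly increasing")
  }
  if (!is.null(labels) && length(labels) != length(beat_times)) {
    hrv_validation_error("`labels` must match `beat_times` in length")
  }
  structure(
    list(beat_times = as.numeric(beat_times),
         labels = if (is.null(labels)) NULL else as.character(labels)),
    class = "beat_series"
  )
}

#' @export
print.beat_series <- function(x, ...) {
  n <- length(x$beat_times)
  cat(sprintf("<beat_series> %d beats", n))
  if (n > 1) {
    cat(sprintf(", span %.3f s, mean rate %.1f bpm",
                x$beat_times[n] - x$beat_times[1],
                60 * (n - 1) / (x$beat_times[n] - x$beat_times[1])))
  }
  cat("\n")
  invisible(x)
}

#' Uniformly sampled instantaneous heart-rate series
#'
#' The substrate of all Poincare analysis: heart rate on a regular time grid
#' (default 1 Hz) with a per-sample validity mask. Samples flagged invalid
#' (e.g. by [filter_ectopic()]) stay in place so the grid remains regular,
#' but are never paired in the Poincare map.
#'
#' @param values Numeric vector of heart rate in bpm. Positions where
#'   `valid` is `FALSE` may hold any value (including `NA`).
#' @param start_time Time of the first sample, seconds (default 0).
#' @param sampling_interval Grid spacing in seconds (default 1, i.e. 1 Hz).
#' @param valid Logical validity mask, same length as `values`.
#'
#' @return An object of class `hr_series` with fields `start_time`,
#'   `sampling_interval`, `values`, `valid`.
#' @seealso [hr_times()], [resample_uniform()], [filter_ectopic()],
#'   [make_pairs()]
#' @export
#' @examples
#' s <- hr_series(c(60, 61, 62, 61))
#' hr_times(s)
hr_series <- function(values, start_time = 0, sampling_interval = 1,
                      valid = rep(TRUE, length(values))) {
  if (!is_number(sampling_interval) || sampling_interval <= 0) {
    hrv_validation_error("`sampling_interval` must be a positive number")
  }
  if (!is_number(start_time)) {
    hrv_validation_error("`start_time` must be a finite number")
  }
  if (!is.logical(valid) || length(valid) != length(values) || anyNA(valid)) {
    hrv_validation_error("`valid` must be a logical mask matching `values`")
  }
  values <- as.numeric(values)
  v <- values[valid]
  if (anyNA(v) || any(!is.finite(v)) || any(v <= 0)) {
    hrv_validation_error("valid heart-rate values must be finite and > 0 bpm")
  }
  structure(
    list(start_time = as.numeric(start_time),
         sampling_interval = as.numeric(sampling_interval),
         values = values, valid = valid),
    class = "hr_series"
  )
}

#' Sample times, duration and end of an `hr_series`
#'
#' @param series An [hr_series()].
#' @return `hr_times()`: numeric vector of sample times (seconds);
#'   `hr_duration()`: time spanned between first and last sample (seconds);
#'   `hr_end()`: time of the last sample.
#' @export
hr_times <- function(series) {
  stopifnot(inherits(series, "hr_series"))
  series$start_time + (seq_along(series$values) - 1L) * series$sampling_interval
}

#' @rdname hr_times
#' @export
hr_duration <- function(series) {
  stopifnot(inherits(series, "hr_series"))
  (length(series$values) - 1L) * series$sampling_interval
}

#' @rdname hr_times
#' @export
hr_end <- function(series) {
  stopifnot(inherits(series, "hr_series"))
  series$start_time + hr_duration(series)
}

#' @export
print.hr_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<hr_series> %d samples at %.3g Hz, t = [%.1f, %.1f] s, %d valid\n",
              n, 1 / x$sampling_interval, x$start_time, hr_end(x),
              sum(x$valid)))
  if (any(x$valid)) {
    v <- x$values[x$valid]
    cat(sprintf("  HR: mean %.1f bpm, range [%.1f, %.1f]\n",
                mean(v), min(v), max(v)))
  }
  invisible(x)
}

#' @export
as.data.frame.hr_series <- function(x, ...) {
  data.frame(time_s = hr_times(x), hr_bpm = x$values, valid = x$valid)
}
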