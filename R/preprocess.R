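#' Ectopic/noise filter configuration
#'
#' Relative-threshold artifact filter used on the 1 Hz heart-rate series:
#' a sample is rejected when it deviates from the most recently accepted
#' sample by more than `relative_threshold` (a fraction of that reference).
#' The default 20% threshold is the standard recommendation for removing
#' ectopic beats and measurement noise from rate series before HRV analysis.
#'
#' @param relative_threshold Fraction in (0, 1); default 0.20.
#' @return An object of class `filter_config`.
#' @seealso [filter_ectopic()]
#' @export
filter_config <- function(relative_threshold = 0.20) {
  if (!is_number(relative_threshold) ||
      relative_threshold <= 0 || relative_threshold >= 1) {
    hrv_config_error("`relative_threshold` must be a fraction in (0, 1)")
  }
  structure(list(relative_threshold = relative_threshold,
                 reference = "previous_accepted"),
            class = "filter_config")
}

#' Instantaneous heart rate from beat times
#'
#' Converts beat occurrence times to an instantaneous heart-rate sample
#' stream: each consecutive beat pair (t_i, t_{i+1}) yields a sample
#' 60 / (t_{i+1} - t_i) bpm, placed at the time of the later beat so the
#' estimate is causal (usable in streaming).
#'
#' @param beats A [beat_series()] with at least 2 beats.
#' @return An [hr_samples()] stream of length `n_beats - 1`.
#' @export
#' @examples
#' beats_to_instantaneous_hr(beat_series(c(0, 0.8, 1.8)))
beats_to_instantaneous_hr <- function(beats) {
  stopifnot(inherits(beats, "beat_series"))
  t <- beats$beat_times
  if (length(t) < 2) hrv_insufficient("need at least 2 beats to derive heart rate")
  rr <- diff(t)
  hr_samples(t[-1], 60 / rr, source_label = "instantaneous HR from beats")
}

#' Resample to a uniform grid
#'
#' Linearly interpolates raw heart-rate samples onto the regular grid
#' `t_k = t_first + k / fs`, `k = 0 .. floor((t_last - t_first) * fs)`.
#' No extrapolation is performed beyond the first/last raw sample.
#' Optionally a centered moving average of `smooth_window` points is applied
#' after interpolation (edge samples use the truncated window); this
#' emulates the smoothed instantaneous-rate conversion commonly applied to
#' annotation-derived heart rate.
#'
#' @param samples An [hr_samples()] with at least 2 samples.
#' @param fs Target sampling frequency in Hz (default 1).
#' @param smooth_window Width of the moving average in samples; 0 or 1
#'   disables smoothing (default 0).
#' @return An [hr_series()] on the uniform grid, all samples valid.
#' @export
#' @examples
#' resample_uniform(hr_samples(c(0, 2), c(60, 62)), fs = 1)
resample_uniform <- function(samples, fs = 1, smooth_window = 0) {
  stopifnot(inherits(samples, "hr_samples"))
  if (!is_number(fs) || fs <= 0) hrv_config_error("`fs` must be positive")
  if (!is_count(smooth_window)) {
    hrv_config_error("`smooth_window` must be a non-negative integer")
  }
  t <- samples$times
  if (length(t) < 2) hrv_insufficient("need at least 2 samples to resample")
  k_max <- floor((t[length(t)] - t[1]) * fs + .time_eps)
  grid <- t[1] + (0:k_max) / fs
  v <- stats::approx(t, samples$values, xout = grid, method = "linear",
                     rule = 1)$y
  if (smooth_window > 1) v <- moving_average_truncated(v, smooth_window)
  hr_series(v, start_time = t[1], sampling_interval = 1 / fs)
}

# Centered moving average; windows at the edges are truncated to what is
# available rather than padded.
moving_average_truncated <- function(v, width) {
  h <- floor(width / 2)
  n <- length(v)
  vapply(seq_len(n), function(i) {
    mean(v[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Remove ectopic/noise samples by relative threshold
#'
#' Single forward pass over the valid samples: the first valid sample is
#' always accepted and seeds the reference; a later sample `x` is rejected
#' iff `|x - r| / r > relative_threshold`, where `r` is the most recently
#' accepted value; accepted samples update `r`. Values are left in place --
#' only the validity mask changes -- so the grid stays regular and rejected
#' samples become gaps that [make_pairs()] will not pair across.
#'
#' @param series An [hr_series()] with at least one valid sample.
#' @param cfg A [filter_config()].
#' @return The series with its validity mask updated.
#' @export
#' @examples
#' s <- hr_series(c(60, 61, 62, 100, 63))
#' filter_ectopic(s)$valid
filter_ectopic <- function(series, cfg = filter_config()) {
  stopifnot(inherits(series, "hr_series"), inherits(cfg, "filter_config"))
  idx <- which(series$valid)
  if (length(idx) == 0) hrv_insufficient("series has no valid samples")
  thr <- cfg$relative_threshold
  mask <- series$valid
  r <- series$values[idx[1]]
  for (i in idx[-1]) {
    x <- series$values[i]
    if (abs(x - r) / r > thr) {
      mask[i] <- FALSE
    } else {
      r <- x
    }
  }
  series$valid <- mask
  series
}
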