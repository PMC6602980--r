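#' Synthetic resting heart-rate configuration
#'
#' Minimal generative model of a resting heart-rate signal on the analysis
#' grid: a constant baseline, a respiratory sinus arrhythmia (RSA)
#' sinusoid, and stationary first-order autoregressive (AR(1)) noise.
#' The AR(1) component gives independently tunable SD1/SD2 through its
#' lag-1 autocorrelation `rho`: in the pure-AR case the population
#' descriptors are `SD1 = sigma * sqrt(1 - rho)` and
#' `SD2 = sigma * sqrt(1 + rho)` (see [expected_descriptors()]).
#'
#' Defaults emulate a healthy resting young adult: 65 bpm baseline, 4 bpm
#' stationary noise SD with lag-1 autocorrelation 0.85 (SD2 several times
#' SD1, as observed at rest), and a 2 bpm RSA sinusoid at 0.25 Hz
#' (15 breaths/min).
#'
#' @param duration Recording length in seconds (must cover at least 2
#'   samples).
#' @param fs Sampling frequency in Hz (default 1).
#' @param baseline_hr Baseline heart rate in bpm.
#' @param noise_sd Stationary standard deviation `sigma` of the AR(1)
#'   noise, bpm.
#' @param lag1_autocorr Lag-1 autocorrelation `rho`, in (-1, 1).
#' @param rsa_amplitude RSA sinusoid amplitude in bpm.
#' @param rsa_freq RSA frequency in Hz; must be below `fs / 2`.
#' @param seed Integer seed; generation is fully reproducible per seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(duration, fs = 1, baseline_hr = 65,
                             noise_sd = 4, lag1_autocorr = 0.85,
                             rsa_amplitude = 2, rsa_freq = 0.25,
                             seed = 1L) {
  if (!is_number(duration) || duration < 2 / fs) {
    hrv_config_error("`duration` must cover at least 2 samples")
  }
  if (!is_number(fs) || fs <= 0) hrv_config_error("`fs` must be positive")
  if (!is_number(baseline_hr) || baseline_hr <= 0) {
    hrv_config_error("`baseline_hr` must be positive")
  }
  if (!is_number(noise_sd) || noise_sd < 0) {
    hrv_config_error("`noise_sd` must be >= 0")
  }
  if (!is_number(lag1_autocorr) || abs(lag1_autocorr) >= 1) {
    hrv_config_error("`lag1_autocorr` must lie in (-1, 1)")
  }
  if (!is_number(rsa_amplitude) || rsa_amplitude < 0) {
    hrv_config_error("`rsa_amplitude` must be >= 0")
  }
  if (!is_number(rsa_freq) || rsa_freq < 0 || rsa_freq >= fs / 2) {
    hrv_config_error("`rsa_freq` must lie in [0, fs/2)")
  }
  if (!is_count(abs(seed))) hrv_config_error("`seed` must be an integer")
  structure(list(duration = duration, fs = fs, baseline_hr = baseline_hr,
                 noise_sd = noise_sd, lag1_autocorr = lag1_autocorr,
                 rsa_amplitude = rsa_amplitude, rsa_freq = rsa_freq,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Anesthesia-transition configuration
#'
#' Emulates the abrupt suppression of heart-rate variability at anesthetic
#' induction: from `t0` onwards, deviations from the known baseline are
#' multiplied by `suppression_factor` and an optional baseline shift is
#' added. `suppression_factor = 1` with zero shift is the identity.
#'
#' @param t0 Induction time in seconds.
#' @param suppression_factor `f` in (0, 1]; post-induction variability is
#'   scaled by this factor.
#' @param baseline_shift Additive post-induction baseline change in bpm
#'   (default 0).
#' @return An object of class `transition_config`.
#' @export
transition_config <- function(t0, suppression_factor, baseline_shift = 0) {
  if (!is_number(t0)) hrv_config_error("`t0` must be a finite number")
  if (!is_number(suppression_factor) || suppression_factor <= 0 ||
      suppression_factor > 1) {
    hrv_config_error("`suppression_factor` must lie in (0, 1]")
  }
  if (!is_number(baseline_shift)) {
    hrv_config_error("`baseline_shift` must be a finite number")
  }
  structure(list(t0 = t0, suppression_factor = suppression_factor,
                 baseline_shift = baseline_shift),
            class = "transition_config")
}

#' Generate a synthetic resting heart-rate series
#'
#' Simulates `HR_t = baseline_hr + rsa_amplitude * sin(2 pi rsa_freq t +
#' phi) + e_t`, with `phi` uniform on `[0, 2 pi)` and `e` a stationary
#' AR(1) process with stationary SD `noise_sd` and lag-1 autocorrelation
#' `lag1_autocorr` (innovation SD `sigma * sqrt(1 - rho^2)`; the initial
#' state is drawn from the stationary distribution). Generation is seeded
#' and bit-reproducible; the caller's RNG state is left untouched.
#'
#' @param cfg A [synthetic_config()].
#' @return An [hr_series()] with attribute `"baseline_hr"` (the known
#'   baseline, used by [inject_transition()]) and `"config"`.
#' @export
#' @examples
#' s <- generate_hr(synthetic_config(duration = 120, seed = 7))
#' print(s)
generate_hr <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- floor(cfg$duration * cfg$fs + .time_eps) + 1L
  t <- (seq_len(n) - 1L) / cfg$fs
  rho <- cfg$lag1_autocorr
  sigma <- cfg$noise_sd
  vals <- withr::with_seed(cfg$seed, {
    phi <- stats::runif(1, 0, 2 * pi)
    e <- if (sigma == 0) {
      numeric(n)
    } else {
      innov <- stats::rnorm(n, sd = sigma * sqrt(1 - rho^2))
      e0 <- stats::rnorm(1, sd = sigma)
      as.numeric(stats::filter(innov, rho, method = "recursive", init = e0))
    }
    cfg$baseline_hr + cfg$rsa_amplitude * sin(2 * pi * cfg$rsa_freq * t + phi) + e
  })
  if (any(vals <= 0)) {
    hrv_config_error(
      "generated heart rate reached <= 0 bpm; choose a higher baseline or lower noise")
  }
  out <- hr_series(vals, start_time = 0, sampling_interval = 1 / cfg$fs)
  attr(out, "baseline_hr") <- cfg$baseline_hr
  attr(out, "config") <- cfg
  out
}

#' Closed-form expected descriptors for the AR(1) generator
#'
#' Population limits of the Poincare descriptors for the pure
#' autoregressive case (`rsa_amplitude = 0`): for a stationary process
#' with SD `sigma` and lag-1 autocorrelation `rho`,
#' `Var(x_t - x_{t+1}) / 2 = sigma^2 (1 - rho)` and
#' `Var(x_t + x_{t+1}) / 2 = sigma^2 (1 + rho)`, hence
#' `SD1 = sigma * sqrt(1 - rho)` and `SD2 = sigma * sqrt(1 + rho)`.
#' These serve as an independent oracle for the estimators.
#'
#' @param cfg A [synthetic_config()] with `rsa_amplitude = 0`.
#' @return A list with `sd1` and `sd2` (bpm).
#' @export
#' @examples
#' expected_descriptors(synthetic_config(60, noise_sd = 1,
#'                                       lag1_autocorr = 0.8,
#'                                       rsa_amplitude = 0))
expected_descriptors <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$rsa_amplitude != 0) {
    hrv_config_error(
      "closed-form descriptors are stated for the pure AR case (rsa_amplitude = 0)")
  }
  list(sd1 = cfg$noise_sd * sqrt(1 - cfg$lag1_autocorr),
       sd2 = cfg$noise_sd * sqrt(1 + cfg$lag1_autocorr))
}

#' Inject an anesthesia-like variability suppression
#'
#' For samples with `t > t0`, deviations from the known baseline are
#' multiplied by the suppression factor and the baseline shift is added;
#' samples at or before `t0` are unchanged.
#'
#' @param series An [hr_series()], typically from [generate_hr()].
#' @param cfg A [transition_config()]; `t0` must lie within the series.
#' @param baseline Baseline heart rate in bpm about which deviations are
#'   scaled; defaults to the series' `"baseline_hr"` attribute, falling
#'   back to the mean of the valid samples at or before `t0`.
#' @return The modified [hr_series()] (attributes preserved).
#' @export
inject_transition <- function(series, cfg, baseline = NULL) {
  stopifnot(inherits(series, "hr_series"), inherits(cfg, "transition_config"))
  t <- hr_times(series)
  if (cfg$t0 < series$start_time - .time_eps || cfg$t0 > hr_end(series) + .time_eps) {
    hrv_range_error(sprintf("t0 = %g s lies outside the recording [%g, %g] s",
                            cfg$t0, series$start_time, hr_end(series)))
  }
  if (is.null(baseline)) baseline <- attr(series, "baseline_hr")
  if (is.null(baseline)) {
    pre <- series$valid & t <= cfg$t0 + .time_eps
    if (!any(pre)) hrv_insufficient("no valid pre-transition samples to estimate the baseline")
    baseline <- mean(series$values[pre])
  }
  post <- t > cfg$t0 + .time_eps
  series$values[post] <- baseline +
    cfg$suppression_factor * (series$values[post] - baseline) +
    cfg$baseline_shift
  series
}

#' Inject ectopic-beat artifacts
#'
#' Multiplies a random subset of samples by `1 + magnitude`, returning the
#' modified series and the injected indices as ground truth for filter
#' tests. The first valid sample is never injected: it seeds the filter
#' reference, and corrupting it would invalidate the whole pass rather than
#' emulate an isolated ectopic beat.
#'
#' @param series An [hr_series()].
#' @param rate Per-sample injection probability, in `[0, 0.5)`.
#' @param magnitude Relative spike size (e.g. 0.5 for +50%).
#' @param seed Integer seed; the draw is reproducible.
#' @return A list with `series` (modified) and `injected` (integer
#'   indices).
#' @export
inject_ectopics <- function(series, rate, magnitude, seed = 1L) {
  stopifnot(inherits(series, "hr_series"))
  if (!is_number(rate) || rate < 0 || rate >= 0.5) {
    hrv_validation_error("`rate` must lie in [0, 0.5)")
  }
  if (!is_number(magnitude) || magnitude <= 0) {
    hrv_validation_error("`magnitude` must be positive")
  }
  n <- length(series$values)
  eligible <- which(series$valid)
  if (length(eligible) > 0) eligible <- eligible[-1]  # never the reference seed
  injected <- integer(0)
  if (rate > 0 && length(eligible) > 0) {
    injected <- withr::with_seed(seed,
      eligible[stats::runif(length(eligible)) < rate])
  }
  series$values[injected] <- series$values[injected] * (1 + magnitude)
  list(series = series, injected = injected)
}

#' Generate a synthetic cohort
#'
#' Generates `n_subjects` independent recordings from a shared resting
#' configuration, optionally applying the same anesthesia transition to
#' every subject. Per-subject seeds are `seed + subject index`, so cohorts
#' are reproducible subject by subject. The default cohort size of 18
#' matches a typical proof-of-concept anesthesia study arm.
#'
#' @param n_subjects Number of subjects (>= 2; default 18).
#' @param resting_cfg A [synthetic_config()]; its `seed` field is ignored
#'   in favour of the derived per-subject seeds.
#' @param transition_cfg A [transition_config()] applied to every subject,
#'   or `NULL` for a resting (control) cohort.
#' @param seed Master integer seed.
#' @return A list with `recordings` (named list of [hr_series()], names
#'   `"S01"`, ...) and `manifest` (data frame with `subject_id`,
#'   `induction_time_s` (`NA` for controls), `stage2_start_s`).
#' @export
generate_cohort <- function(n_subjects = 18, resting_cfg,
                            transition_cfg = NULL, seed = 1L) {
  stopifnot(inherits(resting_cfg, "synthetic_config"))
  if (!is_count(n_subjects) || n_subjects < 2) {
    hrv_config_error("`n_subjects` must be an integer >= 2")
  }
  if (!is.null(transition_cfg)) {
    stopifnot(inherits(transition_cfg, "transition_config"))
  }
  ids <- sprintf("S%02d", seq_len(n_subjects))
  recordings <- vector("list", n_subjects)
  names(recordings) <- ids
  for (i in seq_len(n_subjects)) {
    cfg_i <- resting_cfg
    cfg_i$seed <- as.integer(seed + i)
    s <- generate_hr(cfg_i)
    if (!is.null(transition_cfg)) s <- inject_transition(s, transition_cfg)
    recordings[[i]] <- s
  }
  manifest <- data.frame(
    subject_id = ids,
    induction_time_s = if (is.null(transition_cfg)) NA_real_ else transition_cfg$t0,
    stage2_start_s = 900)
  list(recordings = recordings, manifest = manifest)
}
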