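# Trace-level simulators used by the calibration and time-course modules.

#' Simulate single-molecule photobleaching traces
#'
#' Each trace sits at `amplitude` (+ Gaussian read noise) until a
#' uniform-random bleach frame, then drops to `background`. The bleach
#' frame is drawn uniformly over frames 3 to `n_frames - 1` so that at
#' least two samples exist on both sides of the step.
#'
#' @param n Number of traces.
#' @param amplitude Pre-bleach intensity (a.u.); 2900 matches a single
#'   SEP at room temperature on the reference instrument's scale.
#' @param read_noise_sd Gaussian noise SD (a.u.).
#' @param n_frames Frames per trace.
#' @param seed Optional RNG seed.
#' @param background Post-bleach level (a.u.).
#' @return A list of numeric traces of length `n_frames`.
#' @export
simulate_single_molecule_traces <- function(n, amplitude = 2900,
                                            read_noise_sd = 80,
                                            n_frames = 100, seed = NULL,
                                            background = 0) {
  .assert(n > 0 && n_frames >= 10, "need n > 0 and n_frames >= 10")
  .with_seed(seed, {
    lapply(seq_len(n), function(i) {
      b <- sample(3:(n_frames - 1), 1)
      level <- c(rep(amplitude, b - 1), rep(background, n_frames - b + 1))
      level + stats::rnorm(n_frames, 0, read_noise_sd)
    })
  })
}

#' Simulate an evanescent-field z-series
#'
#' Emulates raising a dye-filled electrode tip in 125 nm steps above the
#' glass: intensity follows `I0 * exp(-z / depth_nm)`, optionally with
#' multiplicative Gaussian noise of coefficient of variation `cv_noise`.
#'
#' @param depth_nm Decay length (nm).
#' @param z_values Heights (nm, >= 0); default 0-625 nm in 125 nm steps.
#' @param cv_noise Multiplicative noise CV (0 = noiseless).
#' @param i0 Intensity at z = 0.
#' @param seed Optional RNG seed.
#' @return A data.frame with `z_nm` and `intensity`.
#' @export
simulate_ztip_series <- function(depth_nm = 151,
                                 z_values = seq(0, 625, by = 125),
                                 cv_noise = 0, i0 = 1, seed = NULL) {
  .assert(all(z_values >= 0), "z_values must be non-negative")
  .assert(depth_nm > 0, "depth_nm must be > 0")
  .with_seed(seed, {
    intensity <- i0 * exp(-z_values / depth_nm)
    if (cv_noise > 0)
      intensity <- intensity *
        (1 + stats::rnorm(length(z_values), 0, cv_noise))
    data.frame(z_nm = as.numeric(z_values), intensity = intensity)
  })
}

#' Simulate the surface-SEP response to U-tube pH exchange
#'
#' Surface SEP fluorescence is quenched while the bath is at pH 6.0. Each
#' transition is modeled as a logistic in time parameterized by its
#' 10-90% duration (`exchange_down_ms` for 7.4 -> 6.0, `exchange_up_ms`
#' for the recovery), sampled on a fine grid independent of the imaging
#' frame rate.
#'
#' @param timeline An [make_timeline()] carrying the pH 6.0 windows.
#' @param exchange_down_ms,exchange_up_ms 10-90% transition durations in
#'   ms (> 0).
#' @param noise_sd Additive Gaussian noise SD (fraction of the pH 7.4
#'   level).
#' @param sample_dt Sampling interval of the returned trace (s).
#' @param quench_residual Fluorescence fraction remaining at pH 6.0.
#' @param seed Optional RNG seed.
#' @return A data.frame with `time` (s) and `intensity` (pH 7.4 level 1).
#' @export
simulate_ph_trace <- function(timeline, exchange_down_ms = 100,
                              exchange_up_ms = 200, noise_sd = 0,
                              sample_dt = 0.001, quench_residual = 0,
                              seed = NULL) {
  stopifnot(inherits(timeline, "acq_timeline"))
  .assert(exchange_down_ms > 0 && exchange_up_ms > 0,
          "exchange times must be > 0")
  tt <- seq(0, max(timeline$frame_times), by = sample_dt)
  # logistic scale from the 10-90% duration: t90 - t10 = s * 2 * log(81)/2
  s_down <- (exchange_down_ms / 1000) / (2 * stats::qlogis(0.9))
  s_up <- (exchange_up_ms / 1000) / (2 * stats::qlogis(0.9))
  act <- rep(0, length(tt))
  for (i in seq_len(nrow(timeline$ph_windows))) {
    w <- timeline$ph_windows[i, ]
    act <- act + stats::plogis((tt - w$start) / s_down) *
      (1 - stats::plogis((tt - (w$start + w$duration)) / s_up))
  }
  intensity <- 1 - (1 - quench_residual) * pmin(act, 1)
  if (noise_sd > 0)
    intensity <- .with_seed(seed, intensity +
                              stats::rnorm(length(tt), 0, noise_sd))
  data.frame(time = tt, intensity = intensity)
}

#' Simulate a stimulus-evoked Syp-SEP intensity time course
#'
#' Baseline-zero trace (on the F - F_before scale) with an instantaneous
#' rise to `peak` at stimulation onset followed by a mono-exponential
#' decay with constant `tau` as exocytosed Syp-SEP disperses and is
#' retrieved; additive Gaussian noise of SD `noise_frac * peak`.
#'
#' @param frame_interval,duration,stim_onset Timing in seconds.
#' @param peak Peak amplitude (a.u.).
#' @param tau Decay time constant (s); ~20 s after a 50-pulse train.
#' @param noise_frac Noise SD as a fraction of the peak.
#' @param seed Optional RNG seed.
#' @return A data.frame with `time` and `intensity`.
#' @export
simulate_stim_trace <- function(frame_interval = 0.5, duration = 40,
                                stim_onset = 5, peak = 1000, tau = 20,
                                noise_frac = 0.02, seed = NULL) {
  .assert(tau > 0 && peak > 0, "peak and tau must be > 0")
  tt <- seq(0, duration, by = frame_interval)
  clean <- ifelse(tt >= stim_onset, peak * exp(-(tt - stim_onset) / tau), 0)
  .with_seed(seed, {
    noisy <- clean + if (noise_frac > 0)
      stats::rnorm(length(tt), 0, noise_frac * peak) else 0
    data.frame(time = tt, intensity = noisy)
  })
}
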