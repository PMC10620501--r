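#' Build an acquisition timeline
#'
#' Describes one TIRF recording: a regular frame grid, an electrical field
#' stimulation (a pulse train at `pulse_rate`), and a schedule of brief
#' extracellular pH 6.0 windows produced by the U-tube perfusion system.
#' Every downstream stage (rendering, window averaging, normalization)
#' indexes frames against this object.
#'
#' A frame at time `t` is assigned to a pH window iff
#' `start < t <= start + duration`; with the standard 120 ms frame interval
#' and 700 ms windows this places exactly 5 frames in each window (e.g. a
#' window opening at 3.0 s contains the frames at 3.12, 3.24, 3.36, 3.48
#' and 3.60 s), of which the later 4 are averaged for analysis.
#'
#' @param frame_interval Frame spacing in seconds (> 0).
#' @param duration Recording length in seconds; frames run from 0 to
#'   `duration` inclusive.
#' @param stim_onset Stimulation onset in seconds (within the recording),
#'   or `NA` for recordings without stimulation.
#' @param n_pulses Number of stimulation pulses.
#' @param ph6_starts Numeric vector of pH 6.0 window opening times (s).
#' @param ph6_duration Duration of each pH 6.0 window in seconds
#'   (default 0.7).
#' @param pulse_rate Stimulation frequency in Hz (default 50).
#' @param exposure Camera exposure per frame in seconds (default
#'   `frame_interval`).
#' @param temperature_C Bath temperature in degrees Celsius; room
#'   temperature is 21-23, near-physiological 31-32.
#' @return An object of class `acq_timeline`: a list with `frame_times`,
#'   `frame_ph` (7.4 or 6.0 per frame), `exposure`, `stim_onset`,
#'   `n_pulses`, `pulse_rate`, `ph_windows` (data.frame with `start`,
#'   `duration`, `ph`), and `temperature_C`.
#' @examples
#' tl <- make_timeline(0.12, 10, stim_onset = 5, n_pulses = 50,
#'                     ph6_starts = 8, ph6_duration = 0.7)
#' sum(tl$frame_ph == 6.0)  # 5 frames inside the window
#' @export
make_timeline <- function(frame_interval, duration, stim_onset = NA,
                          n_pulses = 0, ph6_starts = numeric(0),
                          ph6_duration = 0.7, pulse_rate = 50,
                          exposure = frame_interval, temperature_C = 22) {
  .assert(is.numeric(frame_interval) && frame_interval > 0,
          "frame_interval must be > 0")
  .assert(is.numeric(duration) && duration > 0, "duration must be > 0")
  .assert(n_pulses >= 0, "n_pulses must be >= 0")
  if (!is.na(stim_onset))
    .assert(stim_onset >= 0 && stim_onset <= duration,
            "stim_onset (%g s) outside recording duration (%g s)",
            stim_onset, duration)
  if (length(ph6_starts)) {
    .assert(ph6_duration > 0, "ph6_duration must be > 0")
    .assert(all(ph6_starts >= 0 & ph6_starts + ph6_duration <= duration),
            "pH 6.0 windows must lie within the recording")
    s <- sort(ph6_starts)
    if (length(s) > 1)
      .assert(all(diff(s) >= ph6_duration - .time_eps),
              "pH 6.0 windows overlap")
  }

  frame_times <- seq(0, duration + .time_eps, by = frame_interval)
  windows <- data.frame(start = sort(as.numeric(ph6_starts)),
                        duration = rep(ph6_duration, length(ph6_starts)),
                        ph = rep(6.0, length(ph6_starts)))
  ph <- rep(7.4, length(frame_times))
  for (i in seq_len(nrow(windows))) {
    inside <- frame_times > windows$start[i] + .time_eps &
      frame_times <= windows$start[i] + windows$duration[i] + .time_eps
    ph[inside] <- 6.0
  }

  structure(list(frame_times = frame_times, frame_ph = ph,
                 exposure = exposure, stim_onset = stim_onset,
                 n_pulses = n_pulses, pulse_rate = pulse_rate,
                 ph_windows = windows, temperature_C = temperature_C),
            class = "acq_timeline")
}

#' Frame indices belonging to one pH 6.0 window
#'
#' @param timeline An `acq_timeline`.
#' @param window Window index (row of `timeline$ph_windows`).
#' @return Integer vector of frame indices inside the window, in time order.
#' @export
ph6_window_frames <- function(timeline, window) {
  stopifnot(inherits(timeline, "acq_timeline"))
  .assert(window >= 1 && window <= nrow(timeline$ph_windows),
          "window index %d out of range", window)
  w <- timeline$ph_windows[window, ]
  which(timeline$frame_times > w$start + .time_eps &
          timeline$frame_times <= w$start + w$duration + .time_eps)
}

#' @export
print.acq_timeline <- function(x, ...) {
  cat(sprintf("<acq_timeline> %d frames @ %.3f s, %.1f s total\n",
              length(x$frame_times), diff(x$frame_times[1:2]),
              max(x$frame_times)))
  if (!is.na(x$stim_onset))
    cat(sprintf("  stimulation: %d pulses @ %g Hz at t = %g s\n",
                x$n_pulses, x$pulse_rate, x$stim_onset))
  cat(sprintf("  pH 6.0 windows: %d (%s s)\n", nrow(x$ph_windows),
              paste(signif(x$ph_windows$start, 4), collapse = ", ")))
  cat(sprintf("  temperature: %g C\n", x$temperature_C))
  invisible(x)
}

#' @noRd
n_frames <- function(timeline) length(timeline$frame_times)
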