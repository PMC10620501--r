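# Instrument calibrations: single-molecule intensity by step-bleach
# detection, evanescent-field decay length, and solution-exchange time.

#' Detect photobleaching steps in an intensity trace
#'
#' Piecewise-constant change-point fit by binary segmentation: the split
#' minimizing the residual sum of squares is accepted when the implied
#' level change exceeds the amplitude penalty, then both halves are
#' searched recursively. The default penalty is 3 x a robust noise SD
#' (median absolute deviation of the first differences / sqrt(2)). A
#' single SEP molecule shows exactly one downward step; multi-step
#' traces indicate aggregates.
#'
#' @param trace Intensity trace (length >= 10).
#' @param penalty Minimum |level change| to accept a step (a.u.);
#'   default `3 * mad(diff(trace)) / sqrt(2)`.
#' @param min_seg Minimum segment length between change points.
#' @return A `step_fit` list: `n_steps`, `step_frames` (first frame of
#'   each new level), `amplitudes` (signed level drops; positive =
#'   downward), `levels` (fitted segment means), `residual` (RSS of the
#'   piecewise-constant fit).
#' @export
detect_bleach_steps <- function(trace, penalty = NULL, min_seg = 2) {
  .assert(length(trace) >= 10, "trace must have >= 10 samples")
  if (is.null(penalty))
    penalty <- 3 * stats::mad(diff(trace)) / sqrt(2)

  cps <- sort(.binseg(trace, penalty, min_seg))
  bounds <- c(0, cps, length(trace))
  levels <- vapply(seq_len(length(bounds) - 1), function(i)
    mean(trace[(bounds[i] + 1):bounds[i + 1]]), numeric(1))
  rss <- sum(vapply(seq_len(length(bounds) - 1), function(i)
    sum((trace[(bounds[i] + 1):bounds[i + 1]] - levels[i])^2), numeric(1)))
  structure(list(n_steps = length(cps), step_frames = cps + 1L,
                 amplitudes = if (length(cps)) -diff(levels) else numeric(0),
                 levels = levels, residual = rss),
            class = "step_fit")
}

# Recursive binary segmentation on trace[(lo+1):hi]; returns accepted
# change points as global indices (last frame of the left segment).
#' @noRd
.binseg <- function(trace, penalty, min_seg, lo = 0L, hi = length(trace)) {
  n <- hi - lo
  if (n < 2 * min_seg) return(integer(0))
  x <- trace[(lo + 1):hi]
  cs <- cumsum(x); tot <- cs[n]
  k <- min_seg:(n - min_seg)
  # RSS reduction of splitting after position k (left mean vs right mean)
  red <- (cs[k] - k * tot / n)^2 * n / (k * (n - k))
  kbest <- k[which.max(red)]
  lmean <- cs[kbest] / kbest
  rmean <- (tot - cs[kbest]) / (n - kbest)
  if (max(red) <= 1e-12 || abs(lmean - rmean) <= penalty) return(integer(0))
  c(.binseg(trace, penalty, min_seg, lo, lo + kbest),
    lo + kbest,
    .binseg(trace, penalty, min_seg, lo + kbest, hi))
}

#' Single-molecule intensity from step-bleach traces
#'
#' Retains only traces showing exactly one detected (downward) step —
#' the single-step photobleaching signature of a single molecule — and
#' summarizes their step amplitudes.
#'
#' @param traces List of intensity traces.
#' @param penalty,min_seg Passed to [detect_bleach_steps()].
#' @return A list with `mean`, `sem`, `n` (retained traces), and
#'   `amplitudes`.
#' @export
single_molecule_intensity <- function(traces, penalty = NULL,
                                      min_seg = 2) {
  .assert(length(traces) >= 1, "need at least one trace")
  amps <- numeric(0)
  for (tr in traces) {
    sf <- detect_bleach_steps(tr, penalty = penalty, min_seg = min_seg)
    if (sf$n_steps == 1 && sf$amplitudes[1] > 0)
      amps <- c(amps, sf$amplitudes[1])
  }
  .assert(length(amps) > 0, "no single-step traces retained")
  list(mean = mean(amps),
       sem = if (length(amps) > 1)
         stats::sd(amps) / sqrt(length(amps)) else 0,
       n = length(amps), amplitudes = amps)
}

#' Fit the evanescent-field decay length
#'
#' Least-squares fit of `I0 * exp(-z / lambda)` to a z-series (e.g. a
#' dye-filled electrode tip raised in 125 nm steps); exact on noiseless
#' data. No offset term is included.
#'
#' @param z_values Heights (nm), >= 3 distinct values.
#' @param intensities Positive intensities.
#' @return Fitted decay length `lambda` (nm).
#' @export
fit_length_constant <- function(z_values, intensities) {
  .assert(length(unique(z_values)) >= 3, "need >= 3 distinct z values")
  .assert(length(z_values) == length(intensities), "z/intensity mismatch")
  .assert(all(intensities > 0), "intensities must be positive")
  lfit <- stats::lm(log(intensities) ~ z_values)
  slope <- stats::coef(lfit)[2]
  .assert(is.finite(slope) && slope < 0, "intensities do not decay with z")
  fit <- minpack.lm::nlsLM(
    y ~ i0 * exp(-z / lambda),
    data = data.frame(z = z_values, y = intensities),
    start = list(i0 = unname(exp(stats::coef(lfit)[1])),
                 lambda = unname(-1 / slope)),
    lower = c(i0 = 1e-12, lambda = 1e-6))
  unname(stats::coef(fit)["lambda"])
}

#' Measure the 10-90% solution-exchange time
#'
#' Duration of the quench (`direction = "down"`, pH 7.4 -> 6.0) or
#' recovery (`"up"`) transition between the 10% and 90% levels of the
#' trace's span, with linear interpolation between samples.
#'
#' @param trace Surface-SEP intensity trace spanning the transition.
#' @param times Sample times (s).
#' @param direction `"down"` or `"up"`.
#' @param t_range Optional `c(from, to)` (s) restricting the search to
#'   one transition.
#' @return Transition duration in ms.
#' @export
measure_exchange_time <- function(trace, times,
                                  direction = c("down", "up"),
                                  t_range = NULL) {
  direction <- match.arg(direction)
  .assert(length(trace) == length(times), "times/trace mismatch")
  if (!is.null(t_range)) {
    sel <- times >= t_range[1] & times <= t_range[2]
    trace <- trace[sel]; times <- times[sel]
  }
  .assert(length(trace) >= 3, "trace too short")
  hi <- max(trace); lo <- min(trace)
  .assert(hi > lo, "trace is constant; no transition to measure")
  l10 <- lo + 0.1 * (hi - lo)
  l90 <- lo + 0.9 * (hi - lo)

  cross <- function(level, rising) {
    # first crossing time, linearly interpolated
    for (i in seq_len(length(trace) - 1)) {
      a <- trace[i]; b <- trace[i + 1]
      if ((!rising && a > level && b <= level) ||
          (rising && a < level && b >= level)) {
        f <- (level - a) / (b - a)
        return(times[i] + f * (times[i + 1] - times[i]))
      }
    }
    NA_real_
  }
  if (direction == "down") {
    t90 <- cross(l90, rising = FALSE)
    t10 <- cross(l10, rising = FALSE)
    .assert(!is.na(t90) && !is.na(t10) && t10 >= t90,
            "downward transition not bracketed by the trace")
    (t10 - t90) * 1000
  } else {
    t10 <- cross(l10, rising = TRUE)
    t90 <- cross(l90, rising = TRUE)
    .assert(!is.na(t10) && !is.na(t90) && t90 >= t10,
            "upward transition not bracketed by the trace")
    (t90 - t10) * 1000
  }
}
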