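#' Double-exponential photobleaching model
#'
#' Normalized bleach factor B(t) = a1 * exp(-t / tau1) + a2 * exp(-t / tau2)
#' with a1 + a2 = 1, so B(0) = 1. By convention tau1 <= tau2. The identity
#' model (`bleach_model(1, Inf)`) represents no bleaching.
#'
#' @param a1 Fast-component fraction in \[0, 1\].
#' @param tau1 Fast time constant (s, > 0; `Inf` allowed).
#' @param a2 Slow-component fraction (default `1 - a1`).
#' @param tau2 Slow time constant (s).
#' @return A `bleach_model` list.
#' @export
bleach_model <- function(a1, tau1, a2 = 1 - a1, tau2 = Inf) {
  .assert(abs(a1 + a2 - 1) < 1e-8, "a1 + a2 must equal 1")
  .assert(a1 >= 0 && a2 >= 0, "fractions must be non-negative")
  .assert(tau1 > 0 && tau2 > 0, "time constants must be > 0")
  if (tau1 > tau2) {  # enforce tau1 <= tau2
    tmp <- c(a1, tau1); a1 <- a2; tau1 <- tau2; a2 <- tmp[1]; tau2 <- tmp[2]
  }
  structure(list(a1 = a1, tau1 = tau1, a2 = a2, tau2 = tau2),
            class = "bleach_model")
}

#' Evaluate a bleach model
#'
#' @param model A [bleach_model()].
#' @param t Times (s).
#' @return B(t), the fraction of initial fluorescence remaining.
#' @export
bleach_factor <- function(model, t) {
  stopifnot(inherits(model, "bleach_model"))
  model$a1 * exp(-t / model$tau1) + model$a2 * exp(-t / model$tau2)
}

#' Fit a double-exponential bleach curve
#'
#' Least-squares fit of I(t) = I0 * (a1 exp(-t/tau1) + a2 exp(-t/tau2))
#' to a no-stimulation recording's intensity trace. A constant trace
#' returns the identity model (a1 = 1, tau1 = Inf). Degenerate fits
#' (a2 ~ 0, or tau1 ~ tau2 for an effectively mono-exponential trace) are
#' accepted.
#'
#' @param intensity Positive intensity trace (length >= 8).
#' @param times Frame times (s), same length.
#' @return A [bleach_model()]; the fitted `I0` and residual standard
#'   error are attached as attributes `i0` and `sigma`.
#' @export
fit_bleach <- function(intensity, times = seq_along(intensity) - 1) {
  .assert(length(intensity) >= 8, "trace must have >= 8 samples")
  .assert(all(intensity > 0), "intensity must be positive")
  .assert(length(times) == length(intensity), "times/intensity mismatch")
  if (stats::sd(intensity) < 1e-12 * mean(intensity)) {
    m <- bleach_model(1, Inf)
    attr(m, "i0") <- mean(intensity); attr(m, "sigma") <- 0
    return(m)
  }
  span <- diff(range(times))
  df <- data.frame(t = times, y = intensity)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ i0 * (a1 * exp(-t / tau1) + (1 - a1) * exp(-t / tau2)),
      data = df,
      start = list(i0 = intensity[1], a1 = 0.5, tau1 = span / 10,
                   tau2 = span * 2),
      lower = c(i0 = 0, a1 = 0, tau1 = 1e-6, tau2 = 1e-6),
      upper = c(i0 = Inf, a1 = 1, tau1 = Inf, tau2 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop(sprintf("bleach fit did not converge: %s (trace sd %.3g)",
                 conditionMessage(fit), stats::sd(intensity)), call. = FALSE)
  p <- stats::coef(fit)
  m <- bleach_model(unname(p["a1"]), unname(p["tau1"]),
                    1 - unname(p["a1"]), unname(p["tau2"]))
  attr(m, "i0") <- unname(p["i0"])
  attr(m, "sigma") <- stats::sigma(fit)
  m
}

#' Correct a trace or stack for photobleaching
#'
#' Divides intensities by the normalized bleach factor B(t) at each frame
#' time (bleaching is a multiplicative loss of fluorophores). Correcting
#' the model's own curve returns a flat trace; the identity model leaves
#' the input unchanged.
#'
#' @param x A numeric trace or a [frame_stack()].
#' @param model A [bleach_model()].
#' @param times Frame times for a plain trace (ignored for stacks).
#' @return Corrected object of the same type.
#' @export
correct_bleach <- function(x, model, times = NULL) {
  stopifnot(inherits(model, "bleach_model"))
  if (inherits(x, "frame_stack")) {
    f <- bleach_factor(model, x$timeline$frame_times)
    .assert(all(f > 0), "bleach factor <= 0 within the stack's time range")
    x$pixels <- sweep(x$pixels, 3, f, `/`)
    return(x)
  }
  if (is.null(times)) times <- seq_along(x) - 1
  .assert(length(times) == length(x), "times/trace length mismatch")
  f <- bleach_factor(model, times)
  .assert(all(f > 0), "bleach factor <= 0 within the trace's time range")
  x / f
}

#' Background statistics and detection threshold for one frame
#'
#' Computes the background level and spread and the detection threshold
#' `mean + k * SD`, recomputed per frame ("the mean plus 3 times SD of
#' the background signal in each image"). With an explicit `roi`
#' (a signal-free rectangle or mask) plain mean/SD over the ROI are
#' used. With `roi = NULL` the background is estimated robustly over the
#' whole frame as median and scaled MAD — fluorescent signal occupies a
#' small minority of pixels, so these estimators recover the background
#' moments without a hand-drawn region and without the selection bias a
#' lowest-quantile region would introduce.
#'
#' @param frame Numeric matrix.
#' @param roi `NULL` (robust whole-frame estimate), a logical mask of
#'   `dim(frame)`, or a list `list(rows = c(r1, r2), cols = c(c1, c2))`.
#' @param k Threshold multiplier (default 3).
#' @return A `background_stats` list with `mean`, `sd`, `threshold`,
#'   `k`, and the logical `roi` mask used (whole frame for the robust
#'   estimate).
#' @export
background_threshold <- function(frame, roi = NULL, k = 3) {
  .assert(is.matrix(frame), "frame must be a matrix")
  .assert(k > 0, "k must be > 0")
  if (is.null(roi)) {
    m <- stats::median(frame)
    s <- stats::mad(frame)
    mask <- matrix(TRUE, nrow(frame), ncol(frame))
  } else {
    mask <- .resolve_roi(frame, roi)
    vals <- frame[mask]
    .assert(length(vals) > 0, "background ROI is empty")
    m <- mean(vals)
    s <- if (length(vals) > 1) stats::sd(vals) else 0
  }
  structure(list(mean = m, sd = s, threshold = m + k * s, k = k,
                 roi = mask),
            class = "background_stats")
}

#' @noRd
.resolve_roi <- function(frame, roi) {
  if (is.logical(roi)) {
    .assert(all(dim(roi) == dim(frame)), "roi mask dimension mismatch")
    return(roi)
  }
  .assert(is.list(roi) && !is.null(roi$rows) && !is.null(roi$cols),
          "roi must be NULL, a logical mask, or list(rows=, cols=)")
  .assert(roi$rows[1] >= 1 && roi$rows[2] <= nrow(frame) &&
            roi$cols[1] >= 1 && roi$cols[2] <= ncol(frame),
          "roi rectangle outside the frame")
  mask <- matrix(FALSE, nrow(frame), ncol(frame))
  mask[roi$rows[1]:roi$rows[2], roi$cols[1]:roi$cols[2]] <- TRUE
  mask
}

# ---- drift ----------------------------------------------------------------

# Cross-correlation of two equally sized frames via FFT. If the content
# of `img` equals `ref` translated by (sy, sx) pixels (down, right), the
# correlation peak sits at (sy, sx); a 1-D parabola through the peak and
# its two neighbours refines each axis to sub-pixel precision.
#' @noRd
.xcorr_shift <- function(ref, img) {
  a <- ref - mean(ref); b <- img - mean(img)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)),
                      inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  ny <- nrow(cc); nx <- ncol(cc)
  refine <- function(i, n, get) {
    y0 <- get(if (i == 1) n else i - 1)
    y1 <- get(i)
    y2 <- get(if (i == n) 1 else i + 1)
    den <- y0 - 2 * y1 + y2
    if (abs(den) < 1e-12) 0 else 0.5 * (y0 - y2) / den
  }
  dy <- refine(pk[1], ny, function(i) cc[i, pk[2]])
  dx <- refine(pk[2], nx, function(j) cc[pk[1], j])
  wrap <- function(i, n) if (i - 1 > n / 2) i - 1 - n else i - 1
  # fft(a) * Conj(fft(b)) peaks at minus the content shift of b vs a
  -c(wrap(pk[1], ny) + dy, wrap(pk[2], nx) + dx)
}

# Translate a frame's content by (dy, dx) pixels (fractional allowed):
# out[i, j] = frame[i - dy, j - dx], bilinear between grid points;
# samples falling outside the field are filled with `fill`.
#' @noRd
.translate_frame <- function(frame, dy, dx, fill = mean(frame)) {
  ny <- nrow(frame); nx <- ncol(frame)
  ry <- seq_len(ny) - dy
  cx <- seq_len(nx) - dx
  y0 <- floor(ry); x0 <- floor(cx)
  fy <- ry - y0; fx <- cx - x0
  sample_at <- function(r, c) {
    R <- matrix(r, ny, nx); C <- matrix(c, ny, nx, byrow = TRUE)
    ok <- R >= 1 & R <= ny & C >= 1 & C <= nx
    out <- matrix(fill, ny, nx)
    out[ok] <- frame[cbind(R[ok], C[ok])]
    out
  }
  wfy <- matrix(fy, ny, nx); wfx <- matrix(fx, ny, nx, byrow = TRUE)
  sample_at(y0, x0) * (1 - wfy) * (1 - wfx) +
    sample_at(y0, x0 + 1) * (1 - wfy) * wfx +
    sample_at(y0 + 1, x0) * wfy * (1 - wfx) +
    sample_at(y0 + 1, x0 + 1) * wfy * wfx
}

#' Estimate and correct mechanical stage drift
#'
#' Shifts are estimated on the reference channel (the stable CAST-RFP
#' signal) by cross-correlating every frame against frame 1, with
#' parabolic sub-pixel refinement of the correlation peak. The identical
#' shifts are then applied (bilinear interpolation) to the reference and
#' to every other channel, so all channels stay registered. Pixels
#' exposed by the shift are filled with the frame's background level
#' (median); the number of filled pixels per frame is reported in the
#' drift table.
#'
#' @param reference A [frame_stack()] (typically the CAST channel).
#' @param others Optional list of further [frame_stack()]s sharing the
#'   grid and timeline.
#' @return A list with `drift` (data.frame: `frame`, `dy_px`, `dx_px`,
#'   `filled_px`), `reference` (corrected), and `others` (list of
#'   corrected stacks).
#' @export
estimate_and_correct_drift <- function(reference, others = list()) {
  stopifnot(inherits(reference, "frame_stack"))
  if (inherits(others, "frame_stack")) others <- list(others)
  nt <- dim(reference$pixels)[3]
  ref0 <- get_frame(reference, 1)
  .assert(stats::sd(ref0) > 0, "reference frame 1 has no signal to register")
  for (o in others)
    .assert(all(dim(o$pixels) == dim(reference$pixels)),
            "channel grids/timelines differ")

  shifts <- matrix(0, nt, 2)
  for (i in seq_len(nt)[-1])
    shifts[i, ] <- .xcorr_shift(ref0, get_frame(reference, i))

  correct <- function(stack) {
    filled <- integer(nt)
    for (i in seq_len(nt)) {
      if (any(shifts[i, ] != 0)) {
        fr <- get_frame(stack, i)
        # undo the drift: translate content back by -shift; exposed
        # pixels take the frame's background level (median, robust to
        # the bright signal minority)
        stack$pixels[, , i] <- .translate_frame(fr, -shifts[i, 1],
                                                -shifts[i, 2],
                                                fill = stats::median(fr))
        ny <- nrow(fr); nx <- ncol(fr)
        oy <- min(ny, ceiling(abs(shifts[i, 1])))
        ox <- min(nx, ceiling(abs(shifts[i, 2])))
        filled[i] <- oy * nx + ox * ny - oy * ox
      }
    }
    list(stack = stack, filled = filled)
  }
  ref_c <- correct(reference)
  oth_c <- lapply(others, correct)
  list(drift = data.frame(frame = seq_len(nt), dy_px = shifts[, 1],
                          dx_px = shifts[, 2], filled_px = ref_c$filled),
       reference = ref_c$stack,
       others = lapply(oth_c, `[[`, "stack"))
}
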