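# Measurements: pH 6.0 window averaging, pre-stimulus subtraction,
# exclusion, centroids, signed edge distances, cluster metrics,
# trial displacement, time courses.

#' Average the analyzed frames of one pH 6.0 window
#'
#' Five frames are recorded within each 700 ms pH 6.0 window at the
#' 120 ms high-resolution frame interval; the later four are averaged
#' pixel-wise for quantitative analysis (the first is discarded while the
#' solution exchange completes). The timepoint label is the time of the
#' first averaged frame, e.g. a window opening 3 s after stimulation is
#' analyzed "at 3.24 s".
#'
#' @param stack A [frame_stack()] (SEP channel, preprocessed).
#' @param timeline Its [make_timeline()] (defaults to the stack's).
#' @param window pH window index.
#' @param frames_used Which of the window's frames to average (default
#'   frames 2-5).
#' @return A list with `image` (matrix) and `timepoint_label` (s).
#' @export
average_ph6_window <- function(stack, timeline = stack$timeline, window,
                               frames_used = 2:5) {
  stopifnot(inherits(stack, "frame_stack"))
  fr <- ph6_window_frames(timeline, window)
  .assert(length(fr) >= max(frames_used),
          "window %d holds %d frames; need at least %d",
          window, length(fr), max(frames_used))
  sel <- fr[frames_used]
  img <- apply(stack$pixels[, , sel, drop = FALSE], c(1, 2), mean)
  list(image = img, timepoint_label = timeline$frame_times[sel[1]])
}

#' Subtract the pre-stimulus pH 6.0 image
#'
#' Removes stimulus-insensitive intracellular signal (endoplasmic
#' reticulum, resting endosomes): the post-stimulus pH 6.0 analysis image
#' minus the one recorded at pH 6.0 before the stimulation. Negative
#' values are retained.
#'
#' @param img Post-stimulus analysis image (matrix).
#' @param prestim_img Pre-stimulus pH 6.0 analysis image.
#' @return Difference image.
#' @export
subtract_prestim <- function(img, prestim_img) {
  .assert(all(dim(img) == dim(prestim_img)),
          "image grids differ (%s vs %s)",
          paste(dim(img), collapse = "x"),
          paste(dim(prestim_img), collapse = "x"))
  img - prestim_img
}

#' Flag clusters whose signal rises during the pH 6.0 window
#'
#' A signal increase from the background level while the extracellular pH
#' is 6.0 indicates Syp migrating into the evanescent field from deeper
#' in the terminal rather than fresh endocytosis; such clusters are
#' excluded. Operationalized as: excluded when the last intra-window
#' sample exceeds the first by more than `k * stats$sd`.
#'
#' @param trace Cluster intensity across the window's analyzed frames
#'   (>= 4 samples).
#' @param stats A [background_threshold()] result (supplies the SD).
#' @param k Exclusion multiplier (default 3).
#' @return Logical: `TRUE` if the cluster should be excluded.
#' @export
flag_influx_exclusion <- function(trace, stats, k = 3) {
  .assert(length(trace) >= 4, "need >= 4 intra-window samples")
  (trace[length(trace)] - trace[1]) > k * stats$sd
}

#' Intensity-weighted centroid of a cluster
#'
#' The centroid of the fluorescence intensity of a Syp-SEP positive area
#' is taken as the center of the Syp-SEP containing vesicle(s).
#'
#' @param frame Analysis image.
#' @param cluster A `signal_cluster` (or any object with a `pixels`
#'   matrix).
#' @return Centroid `c(x, y)` in nm.
#' @export
intensity_centroid <- function(frame, cluster) {
  px <- cluster$pixel_size_nm
  .wcentroid_nm(frame, cluster$pixels, px)
}

#' Signed distance from a centroid to the AZLM edge
#'
#' Magnitude is the minimum Euclidean distance from the centroid to the
#' centers of the AZLM boundary pixels; the sign is negative when the
#' centroid lies inside the AZLM mask (exocytosis typically inside,
#' endocytosis outside). With several AZLM regions the nearest is used.
#' No sub-pixel contour interpolation is attempted; accuracy is half a
#' pixel.
#'
#' @param centroid_nm `c(x, y)` in nm.
#' @param azlm One `azlm_region` or a list of them.
#' @return A data.frame with `azlm_label` and `signed_nm`.
#' @export
signed_edge_distance <- function(centroid_nm, azlm) {
  if (inherits(azlm, "azlm_region")) azlm <- list(azlm)
  .assert(length(azlm) > 0, "no AZLM regions")
  .assert(all(is.finite(centroid_nm)), "centroid must be finite")
  best <- NULL
  for (a in azlm) {
    px <- a$pixel_size_nm
    bx <- (a$boundary[, 2] - 1) * px
    by <- (a$boundary[, 1] - 1) * px
    d <- sqrt((bx - centroid_nm[1])^2 + (by - centroid_nm[2])^2)
    dmin <- min(d)
    if (is.null(best) || dmin < abs(best$signed_nm)) {
      # membership of the pixel under the centroid decides the sign
      r <- round(centroid_nm[2] / px) + 1
      c <- round(centroid_nm[1] / px) + 1
      inside <- any(a$pixels[, 1] == r & a$pixels[, 2] == c)
      best <- data.frame(azlm_label = a$label,
                         signed_nm = if (inside) -dmin else dmin)
    }
  }
  best
}

#' Cluster intensity metrics
#'
#' Maximum member-pixel intensity, area, and their ratio (the density
#' measure used to compare endocytosis modes: clathrin-derived vesicles
#' concentrate synaptophysin more than bulk-derived ones).
#'
#' @param frame Analysis image.
#' @param cluster A `signal_cluster`.
#' @return A data.frame with `max_intensity`, `area_um2`, `density`.
#' @export
cluster_metrics <- function(frame, cluster) {
  vals <- frame[cluster$pixels]
  .assert(length(vals) > 0, "empty cluster")
  area <- cluster$area_um2
  data.frame(max_intensity = max(vals), area_um2 = area,
             density = max(vals) / area)
}

#' Rescale an intensity measure between temperatures
#'
#' SEP is brighter at room temperature than at near-physiological
#' temperature (2900 vs 2200 a.u. per molecule, ~32% brighter);
#' PT measurements are put on the RT scale by multiplying with
#' `i_rt / i_pt`.
#'
#' @param value Measured value (PT scale).
#' @param i_rt,i_pt Single-molecule calibration intensities (> 0).
#' @return `value * i_rt / i_pt`.
#' @export
temperature_correct <- function(value, i_rt = 2900, i_pt = 2200) {
  .assert(i_pt > 0 && i_rt > 0, "calibration intensities must be > 0")
  value * i_rt / i_pt
}

#' Nearest-centroid displacement between two centroid sets
#'
#' For each centroid in `set_a`, the Euclidean distance to its nearest
#' neighbour in `set_b`; used to compare endocytosis locations between
#' repeated trials (and between timepoints within a trial).
#'
#' @param set_a,set_b Matrices/data.frames with columns x, y (nm); each
#'   row one centroid.
#' @return Numeric vector of length `nrow(set_a)`.
#' @export
nearest_centroid_displacement <- function(set_a, set_b) {
  set_a <- as.matrix(set_a); set_b <- as.matrix(set_b)
  .assert(nrow(set_a) > 0 && nrow(set_b) > 0, "both sets must be non-empty")
  vapply(seq_len(nrow(set_a)), function(i) {
    min(sqrt((set_b[, 1] - set_a[i, 1])^2 + (set_b[, 2] - set_a[i, 2])^2))
  }, numeric(1))
}

#' Normalized and background-referenced time course
#'
#' `normalized_f` divides by the mean of all pre-stimulus pH 7.4 frames
#' (F/F_pre); `delta_f` subtracts the value at the designated
#' pre-stimulus pH 6.0 timepoint (F - F_before), and may be slightly
#' negative under noise.
#'
#' @param trace Intensity per frame.
#' @param timeline The recording's [make_timeline()] (with `stim_onset`).
#' @param prestim_ph6_value Value of the pre-stimulus pH 6.0 reference
#'   (e.g. the cluster intensity in the pre-stimulus window average); `NA`
#'   leaves `delta_f` as `NA`.
#' @return A data.frame with `time`, `ph`, `f`, `normalized_f`,
#'   `delta_f`.
#' @export
normalized_timecourse <- function(trace, timeline,
                                  prestim_ph6_value = NA) {
  stopifnot(inherits(timeline, "acq_timeline"))
  .assert(length(trace) == n_frames(timeline),
          "trace length %d != %d frames", length(trace),
          n_frames(timeline))
  .assert(!is.na(timeline$stim_onset), "timeline has no stimulation")
  pre <- timeline$frame_times < timeline$stim_onset &
    timeline$frame_ph == 7.4
  .assert(any(pre), "no pre-stimulus pH 7.4 frames")
  f_pre <- mean(trace[pre])
  data.frame(time = timeline$frame_times, ph = timeline$frame_ph,
             f = trace, normalized_f = trace / f_pre,
             delta_f = trace - prestim_ph6_value)
}

#' Fit the post-peak decay time constant
#'
#' Least-squares mono-exponential fit `c + a * exp(-(t - t_start)/tau)`
#' to the segment after `t_start` (the post-stimulus decay of the
#' Syp-SEP signal; about 20 s after a 50-pulse train).
#'
#' @param intensity Trace values.
#' @param times Frame times (s).
#' @param t_start Fit start (s); default the time of the trace maximum.
#' @return Fitted `tau` (s).
#' @export
fit_decay_constant <- function(intensity, times, t_start = NULL) {
  .assert(length(intensity) == length(times), "times/trace mismatch")
  if (is.null(t_start)) t_start <- times[which.max(intensity)]
  sel <- times >= t_start
  .assert(sum(sel) >= 4, "too few post-peak samples")
  y <- intensity[sel]; t <- times[sel] - t_start
  .assert(y[1] > mean(y[t > max(t) / 2]), "trace does not decay")
  a0 <- y[1] - min(y)
  fit <- minpack.lm::nlsLM(y ~ c0 + a * exp(-t / tau),
                           data = data.frame(t = t, y = y),
                           start = list(c0 = min(y), a = a0,
                                        tau = max(t) / 3),
                           lower = c(c0 = -Inf, a = 1e-12, tau = 1e-6),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  unname(stats::coef(fit)["tau"])
}

#' Membrane area ratio of two spherical vesicles
#'
#' Sphere surface area scales with diameter squared, so a vesicle of
#' diameter `d_large` internalizes the membrane of `(d_large/d_small)^2`
#' vesicles of diameter `d_small` (an ultrafast endocytic vesicle of
#' ~100 nm equals 4 synaptic vesicles of ~50 nm).
#'
#' @param d_large,d_small Diameters (> 0), any common unit.
#' @return Unitless area ratio.
#' @export
membrane_area_ratio <- function(d_large, d_small) {
  .assert(all(d_large > 0) && all(d_small > 0), "diameters must be > 0")
  (d_large / d_small)^2
}

#' Correlation between exocytosed and endocytosed signal
#'
#' Pearson correlation of per-cluster peak intensities at pH 7.4 (the
#' exocytosed amount) with the pH 6.0 intensities (the endocytosed
#' amount): the more Syp-SEP is exocytosed, the more is endocytosed.
#'
#' @param peak_ph74,ph6_intensity Paired per-cluster values (n >= 3).
#' @return Pearson r.
#' @export
exo_endo_correlation <- function(peak_ph74, ph6_intensity) {
  .assert(length(peak_ph74) == length(ph6_intensity), "unpaired samples")
  .assert(length(peak_ph74) >= 3, "need n >= 3 pairs")
  .assert(stats::sd(peak_ph74) > 0 && stats::sd(ph6_intensity) > 0,
          "zero variance in one of the variables")
  stats::cor(peak_ph74, ph6_intensity)
}
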