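#' Construct a frame stack
#'
#' One channel's pixel data for a whole recording. Pixels are stored as a
#' 3-D numeric array indexed `[row, col, frame]` (row = y, col = x,
#' 1-based); physical coordinates in nm are measured from the center of
#' pixel (1, 1), so pixel (i, j) sits at ((j-1) * px, (i-1) * px) in
#' (x, y).
#'
#' @param pixels 3-D numeric array `[y, x, t]` (a single matrix is
#'   promoted to a one-frame stack).
#' @param channel `"SEP"` (green, Syp-SEP) or `"CAST"` (red, AZLM marker).
#' @param pixel_size_nm Physical pixel size in nm (> 0).
#' @param timeline The recording's [make_timeline()] object; frame count
#'   must match.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(pixels, channel = c("SEP", "CAST"),
                        pixel_size_nm, timeline) {
  channel <- match.arg(channel)
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1))
  .assert(is.array(pixels) && length(dim(pixels)) == 3,
          "pixels must be a [y, x, t] array")
  .assert(is.numeric(pixel_size_nm) && pixel_size_nm > 0,
          "pixel_size_nm must be > 0")
  stopifnot(inherits(timeline, "acq_timeline"))
  .assert(dim(pixels)[3] == n_frames(timeline),
          "stack has %d frames but timeline has %d",
          dim(pixels)[3], n_frames(timeline))
  structure(list(pixels = pixels, channel = channel,
                 pixel_size_nm = pixel_size_nm, timeline = timeline),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<frame_stack> %s channel, %d x %d px (%.1f nm/px), %d frames\n",
              x$channel, d[1], d[2], x$pixel_size_nm, d[3]))
  invisible(x)
}

#' @noRd
get_frame <- function(stack, i) stack$pixels[, , i]

# ---- serialization helpers (timeline <-> plain list for JSON sidecars) ----

#' @noRd
.timeline_to_list <- function(tl) {
  list(frame_interval = if (n_frames(tl) > 1) diff(tl$frame_times[1:2]) else tl$exposure,
       duration = max(tl$frame_times),
       exposure = tl$exposure,
       stim_onset = tl$stim_onset,
       n_pulses = tl$n_pulses,
       pulse_rate = tl$pulse_rate,
       ph6_starts = tl$ph_windows$start,
       ph6_duration = if (nrow(tl$ph_windows)) tl$ph_windows$duration[1] else 0.7,
       temperature_C = tl$temperature_C)
}

#' @noRd
.timeline_from_list <- function(x) {
  make_timeline(frame_interval = x$frame_interval, duration = x$duration,
                stim_onset = if (is.null(x$stim_onset)) NA else x$stim_onset,
                n_pulses = x$n_pulses %||% 0,
                ph6_starts = as.numeric(x$ph6_starts %||% numeric(0)),
                ph6_duration = x$ph6_duration %||% 0.7,
                pulse_rate = x$pulse_rate %||% 50,
                exposure = x$exposure %||% x$frame_interval,
                temperature_C = x$temperature_C %||% 22)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a frame stack as multi-page TIFF plus JSON sidecar
#'
#' Pixel data are written as one TIFF page per frame. Because float TIFF
#' pages are stored in \[0, 1\], intensities are rescaled on write and the
#' affine transform (`offset`, `scale`) is recorded in a JSON sidecar
#' (`<stem>.json`) together with pixel size, channel and the acquisition
#' timeline; [read_stack()] undoes the transform, so the round trip is
#' lossless up to 32-bit float precision (16-bit integer storage quantizes
#' to 65535 levels).
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF path; the sidecar replaces the extension with
#'   `.json`.
#' @param dtype `"float32"` (default) or `"uint16"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, dtype = c("float32", "uint16")) {
  stopifnot(inherits(stack, "frame_stack"))
  dtype <- match.arg(dtype)
  px <- stack$pixels
  lo <- min(px); hi <- max(px)
  scale <- if (hi > lo) hi - lo else 1
  scaled <- (px - lo) / scale
  pages <- lapply(seq_len(dim(px)[3]), function(i) scaled[, , i])
  bits <- if (dtype == "float32") 32L else 16L
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = bits,
                                   compression = "none", reduce = FALSE))
  sidecar <- list(channel = stack$channel,
                  pixel_size_nm = stack$pixel_size_nm,
                  dtype = dtype, offset = lo, scale = scale,
                  n_frames = dim(px)[3],
                  timeline = .timeline_to_list(stack$timeline))
  jsonlite::write_json(sidecar, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @noRd
.sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' Read a frame stack written by [write_stack()]
#'
#' @param path TIFF path (the JSON sidecar must sit next to it).
#' @param timeline Optional [make_timeline()] overriding the sidecar's;
#'   its frame count must match the page count.
#' @return A [frame_stack()].
#' @export
read_stack <- function(path, timeline = NULL) {
  .assert(file.exists(path), "stack file not found: %s", path)
  sc_path <- .sidecar_path(path)
  .assert(file.exists(sc_path), "sidecar not found: %s", sc_path)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (is.null(timeline)) timeline <- .timeline_from_list(sc$timeline)
  .assert(length(pages) == n_frames(timeline),
          "file has %d pages but timeline has %d frames",
          length(pages), n_frames(timeline))
  px <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) px[, , i] <- pages[[i]]
  px <- px * sc$scale + sc$offset
  frame_stack(px, channel = sc$channel, pixel_size_nm = sc$pixel_size_nm,
              timeline = timeline)
}
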