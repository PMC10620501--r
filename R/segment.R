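# Segmentation: thresholded masks -> AZLM regions and Syp-SEP clusters.
#
# Components use 8-connectivity (a diagonal-touching blob at the
# ~0.098 um^2 scale must not split). Labels are assigned in scan order
# (column-major order of each component's first pixel), which makes every
# downstream tie-break deterministic.

#' Label 8-connected components of a binary mask
#'
#' Union-find over foreground pixels; labels are renumbered 1..n in scan
#' order of each component's first pixel.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of the same shape, 0 = background.
#' @export
label_components <- function(mask) {
  .assert(is.matrix(mask) && is.logical(mask), "mask must be logical matrix")
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  id <- integer(length(mask)); id[idx] <- seq_along(idx)  # compact ids
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  r <- ((idx - 1) %% ny) + 1
  c <- ((idx - 1) %/% ny) + 1
  for (off in list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))) {
    r2 <- r + off[1]; c2 <- c + off[2]
    ok <- r2 >= 1 & r2 <= ny & c2 >= 1 & c2 <= nx
    n2 <- (c2[ok] - 1) * ny + r2[ok]
    both <- id[n2] > 0
    a <- id[idx[ok]][both]; b <- id[n2][both]
    for (k in seq_along(a)) union2(a[k], b[k])
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  first_seen <- !duplicated(roots)
  relabel <- integer(length(idx))
  relabel[roots[first_seen]] <- seq_len(sum(first_seen))
  lab[idx] <- relabel[roots]
  lab
}

# Inner boundary: member pixels with a 4-neighbour outside the component
# (or on the image edge).
#' @noRd
.boundary_pixels <- function(mask, pixels) {
  ny <- nrow(mask); nx <- ncol(mask)
  is_b <- apply(pixels, 1, function(p) {
    r <- p[1]; c <- p[2]
    r == 1 || r == ny || c == 1 || c == nx ||
      !mask[r - 1, c] || !mask[r + 1, c] ||
      !mask[r, c - 1] || !mask[r, c + 1]
  })
  pixels[is_b, , drop = FALSE]
}

# Intensity-weighted centroid of a pixel set, in nm (x, y).
#' @noRd
.wcentroid_nm <- function(frame, pixels, pixel_size_nm) {
  w <- frame[pixels]
  sw <- sum(w)
  .assert(sw > 0, "zero total intensity in region")
  c(x = sum(w * (pixels[, 2] - 1)) / sw * pixel_size_nm,
    y = sum(w * (pixels[, 1] - 1)) / sw * pixel_size_nm)
}

#' @noRd
.px_area_um2 <- function(n_px, pixel_size_nm) n_px * pixel_size_nm^2 / 1e6

#' Detect AZLM regions in a CAST frame
#'
#' Thresholds the frame at `stats$threshold` (strictly above), labels
#' 8-connected components, and keeps those whose area falls inside the
#' inclusive gate `[azlm_area_min_um2, azlm_area_max_um2]` (default
#' 0.098-0.38 um^2). Typically run on the drift-corrected temporal mean
#' of the CAST channel, which is stable over a recording.
#'
#' @param cast_frame Numeric matrix (a CAST frame or temporal mean).
#' @param stats A [background_threshold()] result for this frame.
#' @param config An [analysis_config()].
#' @param pixel_size_nm Physical pixel size (nm).
#' @return A list of `azlm_region` objects (possibly empty), each with
#'   `label`, `pixels` (n x 2 row/col), `area_um2`, `centroid_nm`,
#'   `boundary` (pixel subset), and `pixel_size_nm`.
#' @export
detect_azlm <- function(cast_frame, stats, config = analysis_config(),
                        pixel_size_nm) {
  mask <- cast_frame > stats$threshold
  lab <- label_components(mask)
  out <- list()
  for (l in seq_len(max(lab))) {
    pix <- which(lab == l, arr.ind = TRUE)
    area <- .px_area_um2(nrow(pix), pixel_size_nm)
    if (area < config$azlm_area_min_um2 || area > config$azlm_area_max_um2)
      next
    cmask <- lab == l
    out[[length(out) + 1]] <- structure(
      list(label = length(out) + 1L, pixels = pix, area_um2 = area,
           centroid_nm = .wcentroid_nm(cast_frame, pix, pixel_size_nm),
           boundary = .boundary_pixels(cmask, pix),
           pixel_size_nm = pixel_size_nm),
      class = "azlm_region")
  }
  out
}

#' Detect Syp-SEP signal clusters in an analysis image
#'
#' Contiguous (8-connected) pixels strictly above the threshold with an
#' area strictly greater than `syp_area_min_um2` (default 0.098 um^2)
#' form a cluster; smaller components are dropped.
#'
#' @param sep_frame Numeric matrix (preprocessed: drift- and
#'   bleach-corrected, window-averaged, pre-stimulus-subtracted as
#'   applicable).
#' @param stats A [background_threshold()] result.
#' @param config An [analysis_config()].
#' @param pixel_size_nm Physical pixel size (nm).
#' @param timepoint_label Analysis time (s) carried on each cluster.
#' @return A list of `signal_cluster` objects with `label`, `pixels`,
#'   `area_um2`, `centroid_nm`, `max_intensity`, `sum_intensity`,
#'   `timepoint_label`, `parent_label` (NA unless produced by
#'   [watershed_split()]), and `excluded`.
#' @export
detect_syp_clusters <- function(sep_frame, stats,
                                config = analysis_config(),
                                pixel_size_nm, timepoint_label = NA) {
  mask <- sep_frame > stats$threshold
  lab <- label_components(mask)
  out <- list()
  for (l in seq_len(max(lab))) {
    pix <- which(lab == l, arr.ind = TRUE)
    area <- .px_area_um2(nrow(pix), pixel_size_nm)
    if (area <= config$syp_area_min_um2) next
    out[[length(out) + 1]] <- .make_cluster(sep_frame, pix,
                                            length(out) + 1L,
                                            pixel_size_nm, timepoint_label)
  }
  out
}

#' @noRd
.make_cluster <- function(frame, pixels, label, pixel_size_nm,
                          timepoint_label, parent_label = NA) {
  structure(list(label = label, pixels = pixels,
                 area_um2 = .px_area_um2(nrow(pixels), pixel_size_nm),
                 centroid_nm = .wcentroid_nm(frame, pixels, pixel_size_nm),
                 max_intensity = max(frame[pixels]),
                 sum_intensity = sum(frame[pixels]),
                 timepoint_label = timepoint_label,
                 parent_label = parent_label, excluded = FALSE,
                 pixel_size_nm = pixel_size_nm),
            class = "signal_cluster")
}

# Local maxima of `values` over the masked pixels with their topographic
# prominence (persistence): process pixels in descending order, merging
# superlevel-set components with union-find; when two components meet,
# the lower peak dies with persistence = its height - current level.
# Returns a data.frame of peak pixels (row, col, value, prominence).
#' @noRd
.peak_prominence <- function(values, mask) {
  idx <- which(mask)
  ord <- idx[order(-values[idx], idx)]
  ny <- nrow(values)
  comp <- integer(length(values))        # 0 = unprocessed
  parent <- integer(0); peak_val <- numeric(0); peak_idx <- integer(0)
  prom <- numeric(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (p in ord) {
    r <- ((p - 1) %% ny) + 1; c <- ((p - 1) %/% ny) + 1
    nb <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > ny || c2 < 1 || c2 > ncol(values)) next
      q <- (c2 - 1) * ny + r2
      if (comp[q] > 0) nb <- c(nb, find(comp[q]))
    }
    nb <- unique(nb)
    if (!length(nb)) {                   # new local maximum
      parent <- c(parent, length(parent) + 1L)
      peak_val <- c(peak_val, values[p])
      peak_idx <- c(peak_idx, p)
      prom <- c(prom, NA_real_)
      comp[p] <- length(parent)
    } else {
      # attach to the component with the highest peak (ties: first made)
      keep <- nb[order(-peak_val[nb], nb)][1]
      comp[p] <- keep
      for (r2 in setdiff(nb, keep)) {    # merge; lower peak dies here
        prom[r2] <- peak_val[r2] - values[p]
        parent[r2] <- keep
      }
    }
  }
  alive <- which(is.na(prom))
  prom[alive] <- peak_val[alive] - min(values[idx])
  data.frame(row = ((peak_idx - 1) %% ny) + 1,
             col = ((peak_idx - 1) %/% ny) + 1,
             value = peak_val, prominence = prom)
}

#' Split a merged cluster along watershed lines
#'
#' When a contiguous Syp-SEP positive area contains multiple intensity
#' peaks (several vesicles in close proximity), watershed lines through
#' the local minima between peaks partition it. The cluster's pixels are
#' Gaussian-smoothed (`config$watershed_sigma_px`), local maxima with
#' topographic prominence of at least `prominence` become markers, and
#' pixels are flooded in descending intensity order, each adopting the
#' label of an already-labeled 8-neighbour (plateau and multi-neighbour
#' ties go to the lowest label id). With fewer than two qualifying peaks
#' the cluster is returned unchanged.
#'
#' @param frame The analysis image the cluster was detected in.
#' @param cluster A `signal_cluster` from [detect_syp_clusters()].
#' @param config An [analysis_config()].
#' @param stats Optional [background_threshold()] result; supplies the
#'   default prominence `config$watershed_prominence_sd * stats$sd`.
#' @param prominence Explicit peak prominence threshold (a.u.);
#'   overrides `stats`.
#' @return A list of `signal_cluster`s whose pixel sets partition the
#'   parent; children carry `parent_label = cluster$label`.
#' @export
watershed_split <- function(frame, cluster, config = analysis_config(),
                            stats = NULL, prominence = NULL) {
  stopifnot(inherits(cluster, "signal_cluster"))
  if (is.null(prominence))
    prominence <- if (!is.null(stats))
      config$watershed_prominence_sd * stats$sd else 0

  pix <- cluster$pixels
  pad <- max(2L, ceiling(3 * config$watershed_sigma_px))
  r0 <- max(1L, min(pix[, 1]) - pad); r1 <- min(nrow(frame), max(pix[, 1]) + pad)
  c0 <- max(1L, min(pix[, 2]) - pad); c1 <- min(ncol(frame), max(pix[, 2]) + pad)
  sub <- frame[r0:r1, c0:c1, drop = FALSE]
  mask <- matrix(FALSE, nrow(sub), ncol(sub))
  mask[cbind(pix[, 1] - r0 + 1, pix[, 2] - c0 + 1)] <- TRUE
  floor_val <- min(sub[mask])
  sub[!mask] <- floor_val                 # keep background out of the peaks
  sm <- if (config$watershed_sigma_px > 0)
    .gauss_smooth(sub, config$watershed_sigma_px) else sub

  peaks <- .peak_prominence(sm, mask)
  peaks <- peaks[peaks$prominence >= prominence |
                   peaks$prominence == max(peaks$prominence), , drop = FALSE]
  if (nrow(peaks) < 2) return(list(cluster))
  peaks <- peaks[order((peaks$col - 1) * nrow(sm) + peaks$row), ]  # scan order

  lab <- matrix(0L, nrow(sm), ncol(sm))
  lab[cbind(peaks$row, peaks$col)] <- seq_len(nrow(peaks))
  midx <- which(mask)
  ord <- midx[order(-sm[midx], midx)]
  repeat {
    assigned_any <- FALSE
    for (p in ord) {
      if (lab[p] > 0) next
      r <- ((p - 1) %% nrow(sm)) + 1; c <- ((p - 1) %/% nrow(sm)) + 1
      # adopt the label of the highest labeled neighbour (water reaches
      # the pixel from the steepest side first); equal heights fall to
      # the lower label id
      best <- 0L; best_val <- -Inf
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 1 || r2 > nrow(sm) || c2 < 1 || c2 > ncol(sm)) next
        l2 <- lab[r2, c2]
        if (l2 == 0L) next
        v2 <- sm[r2, c2]
        if (v2 > best_val || (v2 == best_val && l2 < best)) {
          best <- l2; best_val <- v2
        }
      }
      if (best > 0) {
        lab[p] <- best
        assigned_any <- TRUE
      }
    }
    if (all(lab[midx] > 0) || !assigned_any) break
  }

  out <- list()
  for (l in seq_len(nrow(peaks))) {
    cpix <- which(lab == l & mask, arr.ind = TRUE)
    if (!nrow(cpix)) next
    cpix[, 1] <- cpix[, 1] + r0 - 1; cpix[, 2] <- cpix[, 2] + c0 - 1
    out[[length(out) + 1]] <- .make_cluster(
      frame, cpix, length(out) + 1L, cluster$pixel_size_nm,
      cluster$timepoint_label, parent_label = cluster$label)
  }
  out
}

# Gaussian smoothing via EBImage; replicate-pads the input so small
# crops are not wrapped by the circular filter boundary.
#' @noRd
.gauss_smooth <- function(m, sigma) {
  pad <- ceiling(3 * sigma) + 1
  padded <- m[c(rep(1, pad), seq_len(nrow(m)), rep(nrow(m), pad)),
              c(rep(1, pad), seq_len(ncol(m)), rep(ncol(m), pad))]
  sm <- EBImage::gblur(padded, sigma = sigma)
  sm[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))]
}
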