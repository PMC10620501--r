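# Shared fixture builders (all fixtures are generated in code).

px_nm <- 66.7

# A frame with one or more Gaussian blobs; centers in nm (x, y).
gauss_frame <- function(ny = 24, nx = 24, centers, amps, sigma = 130,
                        background = 0, pixel_size_nm = px_nm) {
  xs <- (seq_len(nx) - 1) * pixel_size_nm
  ys <- (seq_len(ny) - 1) * pixel_size_nm
  f <- matrix(background, ny, nx)
  for (i in seq_len(nrow(centers)))
    f <- f + amps[i] * outer(
      exp(-(ys - centers[i, 2])^2 / (2 * sigma^2)),
      exp(-(xs - centers[i, 1])^2 / (2 * sigma^2)))
  f
}

fake_stats <- function(threshold, sd = 1, mean = 0) {
  structure(list(mean = mean, sd = sd, threshold = threshold, k = 3,
                 roi = NULL), class = "background_stats")
}

# Brute-force 8-connected components by queue flood fill (independent of
# label_components' union-find).
flood_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (!mask[i, j] || lab[i, j] > 0) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r < 1 || r > nrow(mask) || c < 1 || c > ncol(mask)) next
        if (mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Brute-force signed edge distance: scan every member pixel, find those
# with an outside 4-neighbour, take the min center distance.
brute_edge_distance <- function(centroid_nm, mask, pixel_size_nm) {
  ny <- nrow(mask); nx <- ncol(mask)
  dmin <- Inf
  for (j in seq_len(nx)) for (i in seq_len(ny)) {
    if (!mask[i, j]) next
    on_edge <- i == 1 || i == ny || j == 1 || j == nx ||
      !mask[i - 1, j] || !mask[i + 1, j] || !mask[i, j - 1] || !mask[i, j + 1]
    if (!on_edge) next
    d <- sqrt(((j - 1) * pixel_size_nm - centroid_nm[1])^2 +
                ((i - 1) * pixel_size_nm - centroid_nm[2])^2)
    if (d < dmin) dmin <- d
  }
  r <- round(centroid_nm[2] / pixel_size_nm) + 1
  c <- round(centroid_nm[1] / pixel_size_nm) + 1
  inside <- r >= 1 && r <= ny && c >= 1 && c <= nx && mask[r, c]
  if (inside) -dmin else dmin
}

# Small two-window timeline for pipeline tests: pre-stimulus pH 6.0
# window plus post-stimulus windows at +3 and +6.96 s, all snapped to
# the 120 ms frame grid (analyzed at +3.24 and +7.20 s).
mini_timeline <- function(duration = 16, stim_onset = 5.04,
                          offsets = c(-4.08, 3, 6.96), n_pulses = 50,
                          temperature_C = 22) {
  make_timeline(0.12, duration, stim_onset = stim_onset,
                n_pulses = n_pulses, ph6_starts = stim_onset + offsets,
                ph6_duration = 0.7, temperature_C = temperature_C)
}

# Ground truth with hand-placed endo events on the annulus (offsets in
# nm outside the disc edge, angles in radians).
annulus_gt <- function(offsets, angles, r0 = sqrt(0.2e6 / pi),
                       amplitude = 64, acid_tau = 30, t_event = 0.5,
                       z_nm = 75, ...) {
  ev <- lapply(seq_along(offsets), function(i)
    gt_event("endo", "CME", t_event = t_event,
             xy_nm = (r0 + offsets[i]) * c(cos(angles[i]), sin(angles[i])),
             z_nm = z_nm, amplitude_molecules = amplitude,
             acidification_tau = acid_tau))
  ground_truth(events = ev, azlm_radius_nm = r0, ...)
}
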