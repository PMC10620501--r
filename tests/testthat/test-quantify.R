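test_that("window averaging uses the later 4 frames and labels correctly", {
  tl <- make_timeline(0.12, 6, stim_onset = 0, n_pulses = 50,
                      ph6_starts = 3.0, ph6_duration = 0.7)
  vals <- rep(0, length(tl$frame_times))
  vals[ph6_window_frames(tl, 1)] <- 1:5
  px <- array(rep(vals, each = 16), dim = c(4, 4, length(vals)))
  st <- frame_stack(px, "SEP", px_nm, tl)
  avg <- average_ph6_window(st, tl, 1)
  expect_true(all(avg$image == mean(2:5)))        # 3.5
  expect_equal(avg$timepoint_label, 3.24, tolerance = 1e-9)

  # too few frames in the window -> error
  tl_short <- make_timeline(0.3, 6, ph6_starts = 3.0, ph6_duration = 0.7)
  st2 <- frame_stack(array(0, dim = c(4, 4, length(tl_short$frame_times))),
                     "SEP", px_nm, tl_short)
  expect_error(average_ph6_window(st2, tl_short, 1), "at least")
})

test_that("pre-stimulus subtraction cancels static structures", {
  static <- gauss_frame(20, 20, centers = rbind(c(400, 400)), amps = 500)
  punctum <- gauss_frame(20, 20, centers = rbind(c(900, 900)), amps = 800)
  expect_true(all(subtract_prestim(static, static) == 0))
  diffimg <- subtract_prestim(static + punctum, static)
  expect_equal(diffimg, punctum, tolerance = 1e-12)
  # only the punctum survives thresholding of the difference image
  cl <- detect_syp_clusters(diffimg, fake_stats(200), analysis_config(),
                            px_nm, 0)
  expect_length(cl, 1)
  expect_lt(sqrt(sum((cl[[1]]$centroid_nm - c(900, 900))^2)), px_nm)
  expect_error(subtract_prestim(static, matrix(0, 5, 5)), "grids differ")
})

test_that("averaging then subtracting cancels any static additive image", {
  tl <- make_timeline(0.12, 6, stim_onset = 2, n_pulses = 50,
                      ph6_starts = c(0.5, 4), ph6_duration = 0.7)
  set.seed(13)
  nfr <- length(tl$frame_times)
  base <- array(rnorm(12 * 12 * nfr, 100, 3), dim = c(12, 12, nfr))
  static <- gauss_frame(12, 12, centers = rbind(c(300, 300)), amps = 700)
  with_static <- sweep(base, c(1, 2), static, `+`)
  s1 <- frame_stack(base, "SEP", px_nm, tl)
  s2 <- frame_stack(with_static, "SEP", px_nm, tl)
  d1 <- subtract_prestim(average_ph6_window(s1, tl, 2)$image,
                         average_ph6_window(s1, tl, 1)$image)
  d2 <- subtract_prestim(average_ph6_window(s2, tl, 2)$image,
                         average_ph6_window(s2, tl, 1)$image)
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("influx exclusion flags rising intra-window traces only", {
  st <- fake_stats(0, sd = 10)
  expect_true(flag_influx_exclusion(c(0, 20, 45, 80), st))    # rising ramp
  expect_false(flag_influx_exclusion(c(50, 52, 49, 51), st))  # flat
  expect_false(flag_influx_exclusion(c(80, 60, 40, 20), st))  # decaying
  expect_error(flag_influx_exclusion(c(1, 2), st), ">= 4")
})

test_that("intensity centroids are exact on constructed patterns", {
  f <- matrix(0, 12, 12)
  f[6, 8] <- 7
  cl <- list(pixels = cbind(6, 8), pixel_size_nm = px_nm)
  expect_equal(intensity_centroid(f, cl), c(x = 7 * px_nm, y = 5 * px_nm))

  # pixels at x-offset 0 (w 1) and 2 (w 3): centroid at 1.5 pixels
  f2 <- matrix(0, 6, 6)
  f2[3, 1] <- 1; f2[3, 3] <- 3
  cl2 <- list(pixels = rbind(c(3, 1), c(3, 3)), pixel_size_nm = px_nm)
  expect_equal(unname(intensity_centroid(f2, cl2)[1]), 1.5 * px_nm)

  # symmetric Gaussian -> its center
  f3 <- gauss_frame(21, 21, centers = rbind(c(10 * px_nm, 10 * px_nm)),
                    amps = 100)
  cl3 <- list(pixels = which(f3 > 1, arr.ind = TRUE), pixel_size_nm = px_nm)
  expect_equal(unname(intensity_centroid(f3, cl3)),
               c(10 * px_nm, 10 * px_nm), tolerance = 1e-6)

  expect_error(intensity_centroid(matrix(0, 4, 4),
                                  list(pixels = cbind(1, 1),
                                       pixel_size_nm = px_nm)),
               "zero total intensity")
})

test_that("signed edge distances match the brute-force oracle", {
  cfg <- analysis_config(azlm_area_min_um2 = 0.01, azlm_area_max_um2 = 5)
  set.seed(17)
  for (i in 1:15) {
    # a random blobby mask
    f <- gauss_frame(20, 20,
                     centers = rbind(runif(2, 300, 900)), amps = 1000,
                     sigma = runif(1, 100, 220))
    az <- detect_azlm(f, fake_stats(300), cfg, px_nm)
    if (!length(az)) next
    pt <- runif(2, 0, 19 * px_nm)
    got <- signed_edge_distance(pt, az)
    mask <- matrix(FALSE, 20, 20)
    mask[az[[1]]$pixels] <- TRUE
    expect_equal(got$signed_nm, brute_edge_distance(pt, mask, px_nm),
                 tolerance = 1e-9)
  }
})

test_that("edge distance signs and magnitudes behave geometrically", {
  # centroid at the center of a ~300 nm-radius disc -> about -300 nm
  r <- 300
  ny <- 21
  mask <- outer(0:(ny - 1), 0:(ny - 1), function(i, j)
    sqrt((i * px_nm - 10 * px_nm)^2 + (j * px_nm - 10 * px_nm)^2) <= r)
  az <- list(structure(list(label = 1L,
                            pixels = which(mask, arr.ind = TRUE),
                            boundary = azlmquant:::.boundary_pixels(
                              mask, which(mask, arr.ind = TRUE)),
                            pixel_size_nm = px_nm),
                       class = "azlm_region"))
  ctr <- c(10 * px_nm, 10 * px_nm)
  d_ctr <- signed_edge_distance(ctr, az)$signed_nm
  expect_lt(d_ctr, 0)
  expect_equal(abs(d_ctr), r, tolerance = px_nm)
  # 100 nm beyond the boundary -> about +100 nm
  out_pt <- ctr + c(r + 100, 0)
  d_out <- signed_edge_distance(out_pt, az)$signed_nm
  expect_gt(d_out, 0)
  expect_equal(d_out, 100, tolerance = px_nm / 2 + 1e-9)
  # on a boundary pixel -> |d| at most half a pixel diagonal
  bpix <- az[[1]]$boundary[1, ]
  bpt <- c((bpix[2] - 1) * px_nm, (bpix[1] - 1) * px_nm)
  expect_lte(abs(signed_edge_distance(bpt, az)$signed_nm),
             px_nm * sqrt(2) / 2)
  expect_error(signed_edge_distance(ctr, list()), "no AZLM")
})

test_that("cluster metrics scale homogeneously and density is max/area", {
  f <- matrix(0, 8, 8); f[4, 4] <- 10
  cl <- list(pixels = cbind(4, 4), area_um2 = px_nm^2 / 1e6,
             pixel_size_nm = px_nm)
  m <- cluster_metrics(f, cl)
  expect_equal(m$density, 10 / (px_nm^2 / 1e6))
  m2 <- cluster_metrics(2 * f, cl)
  expect_equal(m2$max_intensity, 2 * m$max_intensity)
  expect_equal(m2$density, 2 * m$density)
  expect_equal(m2$area_um2, m$area_um2)
})

test_that("temperature correction reproduces the printed RT rescaling", {
  expect_equal(round(temperature_correct(8.3, 2900, 2200), 1), 10.9)
  expect_equal(temperature_correct(5, 1000, 1000), 5)
  expect_equal(temperature_correct(2200, 2900, 2200), 2900)
  # inverse identity
  expect_equal(temperature_correct(temperature_correct(7, 2900, 2200),
                                   2200, 2900), 7)
  expect_error(temperature_correct(1, 2900, 0), "> 0")
})

test_that("nearest-centroid displacement picks the closest partner", {
  a <- rbind(c(0, 0))
  expect_equal(nearest_centroid_displacement(a, rbind(c(300, 400))), 500)
  expect_equal(nearest_centroid_displacement(a, rbind(c(100, 0),
                                                      c(1000, 0))), 100)
  pts <- matrix(runif(10), 5, 2)
  expect_equal(nearest_centroid_displacement(pts, pts), rep(0, 5))
  expect_error(nearest_centroid_displacement(a, a[0, , drop = FALSE]),
               "non-empty")
})

test_that("time courses normalize by the pre-stimulus pH 7.4 mean", {
  tl <- make_timeline(0.5, 20, stim_onset = 5, n_pulses = 50)
  trace <- rep(1000, length(tl$frame_times))
  trace[tl$frame_times >= 5] <- 3000
  tc <- normalized_timecourse(trace, tl, prestim_ph6_value = 1000)
  expect_equal(max(tc$normalized_f), 3)
  expect_equal(tc$delta_f[1], 0)
  expect_equal(max(tc$delta_f), 2000)
  expect_error(normalized_timecourse(trace, make_timeline(0.5, 20)),
               "no stimulation")
})

test_that("simulated pulse-number series stays near-proportional below saturation", {
  peaks <- vapply(c(5, 20, 50), function(p)
    expected_exo_count(p) / expected_exo_count(5), numeric(1))
  expect_equal(peaks, c(1, 4, 10), tolerance = 0.2)
})

test_that("decay constants are recovered from clean and noisy traces", {
  t <- seq(0, 40, by = 0.5)
  expect_equal(fit_decay_constant(1000 * exp(-t / 20), t, 0), 20,
               tolerance = 1e-6)
  expect_equal(fit_decay_constant(1000 * exp(-t / 5), t, 0), 5,
               tolerance = 1e-6)
  tr <- simulate_stim_trace(0.5, 40, 5, 1000, tau = 20,
                            noise_frac = 0.02, seed = 8)
  expect_equal(fit_decay_constant(tr$intensity, tr$time), 20,
               tolerance = 0.1)
  expect_error(fit_decay_constant(seq(0, 39, 1), 0:39, 0), "decay")
})

test_that("membrane area ratio follows the square of the diameter ratio", {
  expect_equal(membrane_area_ratio(100, 50), 4)
  expect_equal(membrane_area_ratio(70, 70), 1)
  expect_equal(membrane_area_ratio(150, 50), 9)
  expect_error(membrane_area_ratio(-1, 50), "> 0")
})

test_that("exo-endo correlation is 1 for proportional pairs and ~0 under independence", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(exo_endo_correlation(x, 2 * x), 1)
  set.seed(19)
  r_null <- replicate(200, exo_endo_correlation(rnorm(50), rnorm(50)))
  expect_lt(quantile(abs(r_null), 0.95), 0.3)
  # endocytosed amount proportional to exocytosed + noise -> clearly positive
  set.seed(20)
  exo <- runif(40, 500, 5000)
  endo <- 0.5 * exo + rnorm(40, 0, 400)
  expect_gt(exo_endo_correlation(exo, endo), 0.5)
  expect_error(exo_endo_correlation(x, rep(1, 5)), "zero variance")
})
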