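test_that("event counts saturate with pulse number and respect edge cases", {
  # monotone increasing and concave in p
  p <- c(5, 20, 50, 125, 300)
  en <- expected_exo_count(p)
  expect_true(all(diff(en) > 0))
  expect_true(all(diff(diff(en / diff(c(0, p)))) < 0) ||
                all(diff(en) / diff(p) == cummin(diff(en) / diff(p))))
  # saturation: 125 pulses yields less than 2.5x the 50-pulse count
  expect_lt(expected_exo_count(125) / expected_exo_count(50), 125 / 50)
  # near-proportional small-pulse regime
  expect_equal(expected_exo_count(20) / expected_exo_count(5),
               4, tolerance = 0.15)

  expect_length(simulate_events(0, seed = 1)$events, 0)
  expect_error(simulate_events(-5), "n_pulses")
})

test_that("UFE only occurs at near-physiological temperature", {
  gt_rt <- simulate_events(50, temperature_C = 22, seed = 3)
  expect_false(any(gt_events_df(gt_rt)$mode == "UFE"))
  gt_pt <- simulate_events(50, temperature_C = 31, seed = 3,
                           mode_mix = c(CME = 0.1, ADBE = 0.1, UFE = 0.8))
  df <- gt_events_df(gt_pt)
  ufe <- df[df$mode == "UFE", ]
  expect_gt(nrow(ufe), 0)
  expect_true(all(ufe$t_event < 0.3))
  slow <- df[df$mode %in% c("CME", "ADBE"), ]
  expect_true(all(slow$t_event >= 0.5 & slow$t_event <= 10))
})

test_that("simulation is deterministic for a fixed seed", {
  a <- simulate_events(50, seed = 42)
  b <- simulate_events(50, seed = 42)
  expect_identical(gt_events_df(a), gt_events_df(b))
  tl <- make_timeline(0.12, 0.5, stim_onset = 0, n_pulses = 5)
  ra <- render_stack(a, tl, seed = 7, dim_px = c(32, 32))
  rb <- render_stack(b, tl, seed = 7, dim_px = c(32, 32))
  expect_identical(ra$pixels, rb$pixels)
  rc <- render_stack(b, tl, seed = 8, dim_px = c(32, 32))
  expect_false(identical(ra$pixels, rc$pixels))
})

test_that("renderer obeys background, quench and axial attenuation", {
  tl <- make_timeline(0.12, 0.5, stim_onset = 0, n_pulses = 5,
                      ph6_starts = 0.24, ph6_duration = 0.24)
  noi <- noise_config(background_level = 100)
  # no events, noise off -> every frame equals background_level
  gt0 <- ground_truth()
  r0 <- render_stack(gt0, tl, noise = noi, apply_noise = FALSE,
                     dim_px = c(16, 16))
  expect_true(all(r0$pixels == 100))

  # one surface fluorophore, quench_residual 0 -> zero contribution at pH 6
  opt <- optics_config(quench_residual = 0)
  exo <- ground_truth(events = list(
    gt_event("exo", "none", 0, c(0, 0), amplitude_molecules = 10,
             diffusion_sigma_rate = 0, surface_decay_tau = Inf)))
  rs <- render_stack(exo, tl, opt, noi, apply_noise = FALSE,
                     dim_px = c(32, 32))
  ph6_frame <- which(tl$frame_ph == 6.0)[1]
  ph74_frame <- which(tl$frame_ph == 7.4)[1]
  expect_equal(sum(rs$pixels[, , ph6_frame] - 100), 0, tolerance = 1e-9)
  expect_gt(sum(rs$pixels[, , ph74_frame] - 100), 0)

  # endocytosed vesicle at z = 150 nm, depth constant 151 nm:
  # integrated blob intensity = amplitude * exp(-150/151)
  endo <- ground_truth(events = list(
    gt_event("endo", "CME", 0, c(0, 0), z_nm = 150,
             amplitude_molecules = 10, acidification_tau = Inf)))
  re <- render_stack(endo, tl, opt, noise = NULL, apply_noise = FALSE,
                     dim_px = c(32, 32))
  amp <- 10 * opt$sep_brightness_rt
  expect_equal(sum(re$pixels[, , 1]), amp * exp(-150 / 151),
               tolerance = 1e-6)
})

test_that("above-threshold puncta in a noise-free pH 6.0 frame match the ground truth", {
  # conservation: well-separated, not-yet-acidified endocytosed vesicles
  # within the evanescent range are each recovered as one punctum
  tl <- make_timeline(0.12, 1.2, stim_onset = 0, n_pulses = 5,
                      ph6_starts = 0.36, ph6_duration = 0.7)
  mk <- function(xy, z) gt_event("endo", "CME", 0.1, xy, z_nm = z,
                                 amplitude_molecules = 64,
                                 acidification_tau = 30)
  gt <- ground_truth(events = list(
    mk(c(-1200, -1200), 50), mk(c(1200, -1200), 100), mk(c(0, 1400), 200),
    mk(c(1200, 1200), 1500)))  # last far beyond ~2 depth constants
  re <- render_stack(gt, tl, noise = NULL, apply_noise = FALSE,
                     dim_px = c(64, 64))
  frame <- re$pixels[, , which(tl$frame_ph == 6.0)[2]]
  cl <- detect_syp_clusters(frame, fake_stats(threshold = 500),
                            analysis_config(), 66.7, 0.48)
  in_range <- sum(vapply(gt$events, function(e)
    e$z_nm <= 2 * 151, logical(1)))
  expect_equal(length(cl), in_range)
})

test_that("z-series follows the exponential exactly and matches the protocol grid", {
  zs <- simulate_ztip_series(151)
  expect_equal(zs$z_nm, seq(0, 625, by = 125))
  expect_equal(zs$intensity[1], 1)                      # z = 0 -> I0
  expect_equal(zs$intensity[zs$z_nm == 151 * 0 + 125] /
                 zs$intensity[1], exp(-125 / 151))
  zs151 <- simulate_ztip_series(151, z_values = 151)
  expect_equal(zs151$intensity, exp(-1))                # z = depth -> I0/e
  expect_error(simulate_ztip_series(151, z_values = -5), "non-negative")
})

test_that("single-molecule traces are single steps with the set amplitude", {
  tr <- simulate_single_molecule_traces(3, amplitude = 2900,
                                        read_noise_sd = 0, n_frames = 50,
                                        seed = 5)
  for (t in tr) {
    expect_equal(sort(unique(t)), c(0, 2900))
    expect_equal(sum(diff(t) != 0), 1)                  # exactly one step
  }
  flat <- simulate_single_molecule_traces(2, amplitude = 0,
                                          read_noise_sd = 0, n_frames = 20,
                                          seed = 5)
  expect_true(all(unlist(flat) == 0))
  a <- simulate_single_molecule_traces(4, seed = 9)
  b <- simulate_single_molecule_traces(4, seed = 9)
  expect_identical(a, b)
})

test_that("pH trace reproduces the configured 10-90% exchange times", {
  tl <- make_timeline(0.12, 8, ph6_starts = 3, ph6_duration = 2)
  tr <- simulate_ph_trace(tl, exchange_down_ms = 100, exchange_up_ms = 200)
  down <- measure_exchange_time(tr$intensity, tr$time, "down",
                                t_range = c(2, 4))
  up <- measure_exchange_time(tr$intensity, tr$time, "up",
                              t_range = c(4.2, 8))
  expect_equal(down, 100, tolerance = 0.02)
  expect_equal(up, 200, tolerance = 0.02)
  # no pH window -> constant trace
  tr0 <- simulate_ph_trace(make_timeline(0.12, 2))
  expect_true(all(tr0$intensity == 1))
})
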