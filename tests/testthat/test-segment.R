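test_that("component labelling agrees with a brute-force flood fill", {
  set.seed(7)
  for (i in 1:20) {
    mask <- matrix(runif(24 * 24) < 0.35, 24, 24)
    lab <- label_components(mask)
    oracle <- flood_components(mask)
    expect_equal(max(lab), max(oracle))
    # identical partitions up to label names
    for (l in seq_len(max(lab)))
      expect_equal(length(unique(oracle[lab == l])), 1)
  }
})

test_that("diagonally touching pixels form one component (8-connectivity)", {
  mask <- matrix(FALSE, 5, 5)
  mask[1, 1] <- TRUE; mask[2, 2] <- TRUE; mask[3, 3] <- TRUE
  expect_equal(max(label_components(mask)), 1)
})

test_that("AZLM detection applies the inclusive area gate", {
  cfg <- analysis_config()
  # rendered disc of area 0.2 um^2 -> exactly one region
  r0 <- sqrt(0.2e6 / pi)
  opt <- optics_config()
  gt <- ground_truth(azlm_radius_nm = r0, cast_peak = 1000)
  tl <- make_timeline(0.12, 0.12)
  cast <- render_stack(gt, tl, opt, noise = NULL, channel = "CAST",
                       apply_noise = FALSE, dim_px = c(48, 48))
  frame <- cast$pixels[, , 1]
  az <- detect_azlm(frame, fake_stats(threshold = 500), cfg,
                    opt$pixel_size_nm)
  expect_length(az, 1)
  expect_gte(az[[1]]$area_um2, 0.098)
  expect_lte(az[[1]]$area_um2, 0.38)
  expect_true(all(az[[1]]$boundary[, 1] %in% az[[1]]$pixels[, 1]))

  # a mask of 0.05 um^2 falls below the gate
  n_small <- floor(0.05e6 / px_nm^2)
  small <- matrix(0, 24, 24)
  small[cbind(10, 5 + seq_len(n_small))] <- 1000
  expect_length(detect_azlm(small, fake_stats(500), cfg, px_nm), 0)

  # shrinking the gate never adds regions
  wide <- detect_azlm(frame, fake_stats(500), cfg, opt$pixel_size_nm)
  narrow <- detect_azlm(frame, fake_stats(500),
                        analysis_config(azlm_area_min_um2 = 0.15,
                                        azlm_area_max_um2 = 0.25),
                        opt$pixel_size_nm)
  expect_lte(length(narrow), length(wide))
})

test_that("pure-noise frames rarely produce AZLM detections", {
  cfg <- analysis_config()
  set.seed(21)
  spurious <- 0
  for (i in 1:20) {
    f <- matrix(rnorm(48 * 48, 100, 10), 48, 48)
    st <- background_threshold(f, k = 3)
    spurious <- spurious + length(detect_azlm(f, st, cfg, px_nm))
  }
  expect_lte(spurious, 1)
})

test_that("Syp cluster gate is strict and empty frames give empty lists", {
  cfg <- analysis_config()
  # bright blob of ~0.15 um^2 above threshold -> one cluster
  blob <- gauss_frame(24, 24, centers = rbind(c(800, 800)), amps = 1000,
                      sigma = 130)
  cl <- detect_syp_clusters(blob, fake_stats(threshold = 240), cfg,
                            px_nm, 3.24)
  expect_length(cl, 1)
  expect_gt(cl[[1]]$area_um2, 0.098)
  expect_equal(cl[[1]]$timepoint_label, 3.24)
  expect_equal(cl[[1]]$max_intensity, max(blob))

  # a component of exactly 0.08 um^2 (18 px) is dropped
  f <- matrix(0, 24, 24)
  f[cbind(12, 3 + seq_len(18))] <- 1000
  expect_length(detect_syp_clusters(f, fake_stats(500), cfg, px_nm, 0), 0)

  empty <- matrix(0, 16, 16)
  expect_length(detect_syp_clusters(empty, fake_stats(10), cfg, px_nm, 0), 0)
})

test_that("watershed split partitions twin peaks along the equidistant valley", {
  cfg <- analysis_config()
  f <- gauss_frame(24, 24, centers = rbind(c(500, 800), c(1000, 800)),
                   amps = c(1000, 1000))
  cl <- detect_syp_clusters(f, fake_stats(50, sd = 10), cfg, px_nm, 0)
  expect_length(cl, 1)
  ch <- watershed_split(f, cl[[1]], cfg, prominence = 100)
  expect_length(ch, 2)
  # partition: union equals parent, children disjoint
  parent_keys <- sort(cl[[1]]$pixels[, 1] * 1000 + cl[[1]]$pixels[, 2])
  child_keys <- sort(unlist(lapply(ch, function(c)
    c$pixels[, 1] * 1000 + c$pixels[, 2])))
  expect_equal(child_keys, parent_keys)
  expect_true(all(vapply(ch, function(c) c$parent_label == cl[[1]]$label,
                         logical(1))))
  # the watershed line lies within 1 px of the midpoint (x = 750 nm)
  max1 <- max(ch[[1]]$pixels[, 2]); min2 <- min(ch[[2]]$pixels[, 2])
  mid_col <- 750 / px_nm + 1
  expect_lte(abs(max1 - mid_col), 1.6)
  expect_lte(abs(min2 - mid_col), 1.6)

  # single Gaussian -> unchanged
  f1 <- gauss_frame(24, 24, centers = rbind(c(800, 800)), amps = 1000)
  cl1 <- detect_syp_clusters(f1, fake_stats(50, sd = 10), cfg, px_nm, 0)
  ch1 <- watershed_split(f1, cl1[[1]], cfg, prominence = 100)
  expect_length(ch1, 1)
  expect_equal(ch1[[1]]$pixels, cl1[[1]]$pixels)
})

test_that("watershed partition invariant holds on random multi-blob images", {
  cfg <- analysis_config()
  set.seed(31)
  for (i in 1:10) {
    k <- sample(2:3, 1)
    centers <- cbind(runif(k, 300, 1300), runif(k, 300, 1300))
    # enforce min separation so blobs merge but peaks stay distinct
    if (min(dist(centers)) < 350) next
    f <- gauss_frame(26, 26, centers = centers,
                     amps = runif(k, 800, 1200), sigma = 150)
    cl <- detect_syp_clusters(f, fake_stats(60, sd = 10), cfg, px_nm, 0)
    for (parent in cl) {
      ch <- watershed_split(f, parent, cfg, prominence = 50)
      pk <- sort(parent$pixels[, 1] * 1e4 + parent$pixels[, 2])
      ck <- sort(unlist(lapply(ch, function(c)
        c$pixels[, 1] * 1e4 + c$pixels[, 2])))
      expect_equal(ck, pk)   # union = parent and disjoint (keys unique)
      expect_equal(anyDuplicated(ck), 0)
    }
  }
})

test_that("watershed child count matches EBImage's watershed on twin peaks", {
  cfg <- analysis_config()
  f <- gauss_frame(24, 24, centers = rbind(c(500, 800), c(1000, 800)),
                   amps = c(1000, 900))
  cl <- detect_syp_clusters(f, fake_stats(50, sd = 10), cfg, px_nm, 0)
  ch <- watershed_split(f, cl[[1]], cfg, prominence = 100)
  fm <- f; fm[fm < 50] <- 0
  ref <- EBImage::watershed(EBImage::Image(fm), tolerance = 100)
  n_ref <- length(setdiff(unique(as.integer(EBImage::imageData(ref))), 0L))
  expect_equal(length(ch), n_ref)
})

test_that("segmentation is equivariant to integer translation", {
  cfg <- analysis_config()
  f <- gauss_frame(30, 30, centers = rbind(c(700, 700)), amps = 1000,
                   sigma = 110)
  f2 <- azlmquant:::.translate_frame(f, 3, 4, fill = 0)
  cl <- detect_syp_clusters(f, fake_stats(280), cfg, px_nm, 0)
  cl2 <- detect_syp_clusters(f2, fake_stats(280), cfg, px_nm, 0)
  expect_length(cl2, length(cl))
  shifted <- cl[[1]]$pixels
  shifted[, 1] <- shifted[, 1] + 3; shifted[, 2] <- shifted[, 2] + 4
  expect_equal(cl2[[1]]$pixels[order(cl2[[1]]$pixels[, 1],
                                     cl2[[1]]$pixels[, 2]), ],
               shifted[order(shifted[, 1], shifted[, 2]), ],
               ignore_attr = TRUE)
  expect_equal(cl2[[1]]$centroid_nm,
               cl[[1]]$centroid_nm + c(4, 3) * px_nm, tolerance = 1e-9)
})
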