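# Orchestration: simulate -> preprocess -> segment -> quantify over one
# or many recordings, with reproducible run manifests.

#' Default simulation scenario
#'
#' A 50-pulse room-temperature recording at the high-resolution frame
#' interval (120 ms), with one pre-stimulus pH 6.0 window and
#' post-stimulus windows opening about 3, 7, 15, 27 and 39 s after
#' onset. The simulator keeps one continuous 120 ms frame grid for the
#' whole recording, so window openings are snapped to that grid; the
#' first analyzed frame of a window opening at +3 s then falls at
#' +3.24 s, matching the analysis convention.
#'
#' @param n_pulses Number of stimulation pulses.
#' @param temperature_C Bath temperature.
#' @param duration,stim_onset,frame_interval Timing (s); `stim_onset`
#'   and the window openings should sit on the frame grid.
#' @param ph6_offsets Window opening times relative to stimulation onset
#'   (s); negative = before.
#' @return An [make_timeline()] object.
#' @export
scenario_timeline <- function(n_pulses = 50, temperature_C = 22,
                              duration = 46, stim_onset = 5.04,
                              frame_interval = 0.12,
                              ph6_offsets = c(-4.08, 3, 6.96, 15, 27, 39)) {
  make_timeline(frame_interval = frame_interval, duration = duration,
                stim_onset = stim_onset, n_pulses = n_pulses,
                ph6_starts = stim_onset + ph6_offsets,
                ph6_duration = 0.7, pulse_rate = 50,
                temperature_C = temperature_C)
}

#' Simulate a recording and write it to disk
#'
#' Generates ground-truth events, renders both channels, and writes
#' `sep.tif`, `cast.tif` (with JSON sidecars) plus `ground_truth.json`
#' holding the event list, simulation parameters and the seed — enough
#' to score every downstream measurement. Deterministic for a fixed
#' seed.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed RNG seed for the whole simulation.
#' @param timeline An [make_timeline()]; default [scenario_timeline()].
#' @param optics,noise [optics_config()] / [noise_config()].
#' @param dim_px Field size `c(ny, nx)`.
#' @param ... Passed to [simulate_events()] (n_pulses and temperature
#'   default to the timeline's).
#' @return Invisibly, a list with `gt`, `sep`, `cast`, and the file
#'   paths.
#' @export
run_simulation <- function(out_dir, seed = 1,
                           timeline = scenario_timeline(),
                           optics = optics_config(),
                           noise = noise_config(),
                           dim_px = c(64, 64), ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  args <- list(...)
  if (is.null(args$n_pulses)) args$n_pulses <- timeline$n_pulses
  if (is.null(args$temperature_C)) args$temperature_C <- timeline$temperature_C
  gt <- do.call(simulate_events, c(args, list(seed = seed)))
  sep <- render_stack(gt, timeline, optics, noise, channel = "SEP",
                      seed = seed + 1L, dim_px = dim_px)
  cast <- render_stack(gt, timeline, optics, noise, channel = "CAST",
                       seed = seed + 2L, dim_px = dim_px)
  sep_path <- file.path(out_dir, "sep.tif")
  cast_path <- file.path(out_dir, "cast.tif")
  write_stack(sep, sep_path)
  write_stack(cast, cast_path)
  gt_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(
    list(seed = seed, events = gt_events_df(gt),
         azlm_radius_nm = gt$azlm_radius_nm,
         azlm_center_nm = gt$azlm_center_nm,
         drift_nm_per_s = gt$drift_nm_per_s,
         bleach = unclass(gt$bleach),
         exchange_down_ms = gt$exchange_down_ms,
         exchange_up_ms = gt$exchange_up_ms,
         temperature_C = gt$temperature_C,
         optics = unclass(optics), noise = unclass(noise)),
    gt_path, auto_unbox = TRUE, digits = NA)
  invisible(list(gt = gt, sep = sep, cast = cast,
                 paths = c(sep = sep_path, cast = cast_path,
                           ground_truth = gt_path)))
}

#' Run the full analysis over one recording
#'
#' Stage order: drift correction (estimated on CAST, applied to both
#' channels) -> photobleach correction (optional model) -> per-image
#' background thresholding -> AZLM detection on the temporal-mean CAST
#' image -> pH 6.0 window averaging (later 4 of 5 frames) ->
#' pre-stimulus subtraction -> cluster detection and watershed splitting
#' -> influx exclusion -> centroid / edge-distance / metric measurement.
#'
#' @param sep_stack,cast_stack [frame_stack()]s sharing grid and
#'   timeline.
#' @param config An [analysis_config()].
#' @param bleach Optional [bleach_model()] for the SEP channel (e.g.
#'   fitted with [fit_bleach()] on a no-stimulation recording); `NULL`
#'   skips the correction.
#' @param out_dir Optional directory; when given, tidy CSVs
#'   (`edge_distances.csv`, `cluster_metrics.csv`, `timecourses.csv`,
#'   `drift.csv`) and `manifest.json` are written there.
#' @param recording_id Identifier carried into every output row.
#' @return A list with `edge_distances`, `cluster_metrics`,
#'   `timecourses`, `drift`, `azlm` (regions), `clusters`, and
#'   `manifest`.
#' @export
run_analysis <- function(sep_stack, cast_stack,
                         config = analysis_config(), bleach = NULL,
                         out_dir = NULL, recording_id = "rec1") {
  .assert(!is.null(sep_stack) && inherits(sep_stack, "frame_stack"),
          "missing or invalid SEP channel stack")
  .assert(!is.null(cast_stack) && inherits(cast_stack, "frame_stack"),
          "missing or invalid CAST channel stack")
  .assert(sep_stack$channel == "SEP", "sep_stack is not the SEP channel")
  .assert(cast_stack$channel == "CAST",
          "cast_stack is not the CAST channel")
  .assert(all(dim(sep_stack$pixels) == dim(cast_stack$pixels)),
          "channel grids differ")
  .assert(isTRUE(all.equal(sep_stack$timeline$frame_times,
                           cast_stack$timeline$frame_times)),
          "channel timelines differ")
  tl <- sep_stack$timeline
  px <- sep_stack$pixel_size_nm

  ## 1. drift, estimated on the stable CAST channel
  dc <- estimate_and_correct_drift(cast_stack, list(sep_stack))
  cast_c <- dc$reference
  sep_c <- dc$others[[1]]

  ## 2. photobleach correction (SEP only; RFP bleaching not modeled)
  if (!is.null(bleach)) sep_c <- correct_bleach(sep_c, bleach)

  ## 3. AZLM on the drift-reference CAST frame (CAST is stable over a
  ##    recording; the threshold is computed per image, so detection uses
  ##    one image rather than a temporal mean whose lower noise would
  ##    rescale the mean + k*SD threshold)
  cast_img <- get_frame(cast_c, 1)
  cast_stats <- background_threshold(cast_img,
                                     roi = config$background_roi,
                                     k = config$threshold_k_sd)
  azlm <- detect_azlm(cast_img, cast_stats, config, px)

  ## 4-7. per-window averaging, subtraction, segmentation, exclusion
  wins <- tl$ph_windows
  pre_idx <- which(wins$start < tl$stim_onset)
  .assert(length(pre_idx) > 0, "no pre-stimulus pH 6.0 window")
  pre_idx <- pre_idx[length(pre_idx)]
  pre_avg <- average_ph6_window(sep_c, tl, pre_idx,
                                config$ph6_frames_used)
  post_idx <- setdiff(seq_len(nrow(wins)), pre_idx)

  edge_rows <- list(); metric_rows <- list(); clusters_all <- list()
  for (wi in post_idx) {
    avg <- average_ph6_window(sep_c, tl, wi, config$ph6_frames_used)
    img <- subtract_prestim(avg$image, pre_avg$image)
    stats <- background_threshold(img, roi = config$background_roi,
                                  k = config$threshold_k_sd)
    clusters <- detect_syp_clusters(img, stats, config, px,
                                    timepoint_label = avg$timepoint_label)
    split <- list()
    for (cl in clusters)
      split <- c(split, watershed_split(img, cl, config, stats))
    wframes <- ph6_window_frames(tl, wi)[config$ph6_frames_used]
    for (cl in split) {
      tr <- vapply(wframes, function(fi)
        sum(sep_c$pixels[, , fi][cl$pixels]), numeric(1))
      cl$excluded <- flag_influx_exclusion(tr, stats,
                                           config$exclusion_k_sd)
      clusters_all[[length(clusters_all) + 1]] <- cl
      met <- cluster_metrics(img, cl)
      cen <- intensity_centroid(img, cl)
      ed <- if (length(azlm)) signed_edge_distance(cen, azlm) else
        data.frame(azlm_label = NA, signed_nm = NA)
      base <- data.frame(recording_id = recording_id,
                         timepoint_label = avg$timepoint_label,
                         cluster_label = cl$label,
                         parent_label = cl$parent_label,
                         excluded = cl$excluded)
      edge_rows[[length(edge_rows) + 1]] <-
        cbind(base, centroid_x_nm = cen[1], centroid_y_nm = cen[2], ed)
      metric_rows[[length(metric_rows) + 1]] <- cbind(base, met)
    }
  }
  edge_distances <- if (length(edge_rows)) do.call(rbind, edge_rows) else
    data.frame()
  metrics <- if (length(metric_rows)) do.call(rbind, metric_rows) else
    data.frame()

  ## 8. whole-field time course
  field_trace <- apply(sep_c$pixels, 3, sum)
  pre_ph6 <- ph6_window_frames(tl, pre_idx)[config$ph6_frames_used]
  tc <- normalized_timecourse(field_trace, tl,
                              prestim_ph6_value = mean(field_trace[pre_ph6]))
  tc$recording_id <- recording_id

  manifest <- list(
    recording_id = recording_id,
    package_version = as.character(utils::packageVersion("azlmquant")),
    config = unclass(config),
    n_frames = n_frames(tl),
    n_azlm = length(azlm),
    n_clusters = length(clusters_all),
    bleach = if (is.null(bleach)) NULL else unclass(bleach))

  res <- list(edge_distances = edge_distances, cluster_metrics = metrics,
              timecourses = tc, drift = dc$drift, azlm = azlm,
              clusters = clusters_all, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(edge_distances,
                     file.path(out_dir, "edge_distances.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "cluster_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(tc, file.path(out_dir, "timecourses.csv"),
                     row.names = FALSE)
    utils::write.csv(dc$drift, file.path(out_dir, "drift.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    res$manifest_hash <- unname(tools::md5sum(file.path(out_dir,
                                                        "manifest.json")))
  }
  res
}

#' Compare endocytosis locations across trials
#'
#' For each timepoint present in both trials, the nearest-centroid
#' displacement from every (non-excluded) cluster of trial A to trial B;
#' additionally, within trial A, displacements between consecutive
#' timepoints (events persisting across timepoints give smaller
#' within-trial distances than the trial-to-trial ones).
#'
#' @param results_a,results_b `edge_distances` tables from
#'   [run_analysis()] (or any data.frame with `timepoint_label`,
#'   `centroid_x_nm`, `centroid_y_nm`, `excluded`).
#' @return A data.frame with `comparison` ("between_trials" or
#'   "within_trial"), `timepoint_label`, and `displacement_nm`.
#' @export
compare_trials <- function(results_a, results_b) {
  .assert(nrow(results_a) > 0 && nrow(results_b) > 0,
          "empty input tables")
  keep <- function(d) d[!d$excluded, , drop = FALSE]
  a <- keep(results_a); b <- keep(results_b)
  .assert(nrow(a) > 0 && nrow(b) > 0, "no non-excluded clusters")
  rows <- list()
  for (tp in intersect(unique(a$timepoint_label),
                       unique(b$timepoint_label))) {
    ca <- a[a$timepoint_label == tp, c("centroid_x_nm", "centroid_y_nm")]
    cb <- b[b$timepoint_label == tp, c("centroid_x_nm", "centroid_y_nm")]
    if (!nrow(ca) || !nrow(cb)) next
    d <- nearest_centroid_displacement(ca, cb)
    rows[[length(rows) + 1]] <- data.frame(
      comparison = "between_trials", timepoint_label = tp,
      displacement_nm = d)
  }
  tps <- sort(unique(a$timepoint_label))
  if (length(tps) > 1) {
    for (i in seq_len(length(tps) - 1)) {
      c1 <- a[a$timepoint_label == tps[i],
              c("centroid_x_nm", "centroid_y_nm")]
      c2 <- a[a$timepoint_label == tps[i + 1],
              c("centroid_x_nm", "centroid_y_nm")]
      if (!nrow(c1) || !nrow(c2)) next
      d <- nearest_centroid_displacement(c1, c2)
      rows[[length(rows) + 1]] <- data.frame(
        comparison = "within_trial", timepoint_label = tps[i],
        displacement_nm = d)
    }
  }
  .assert(length(rows) > 0, "no comparable timepoints between the trials")
  do.call(rbind, rows)
}
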