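#' Analysis configuration
#'
#' All constants of the measurement procedure live here rather than being
#' hard-coded: the AZLM area gate (inclusive 0.098-0.38 um^2 in the CAST
#' channel), the Syp-SEP cluster minimum area (strictly > 0.098 um^2), the
#' background threshold multiplier k (threshold = background mean + k * SD,
#' default 3), which frames of each 5-frame pH 6.0 window are analyzed
#' (the later 4), watershed settings, and the influx-exclusion multiplier.
#'
#' @param azlm_area_min_um2,azlm_area_max_um2 Inclusive CAST area gate in
#'   um^2 defining an AZLM.
#' @param syp_area_min_um2 Strict lower area bound for Syp-SEP clusters.
#' @param threshold_k_sd Background threshold multiplier k.
#' @param ph6_frames_used Integer indices of the frames used within each
#'   pH 6.0 window (1 = first frame of the window).
#' @param background_roi Either `NULL` (automatic robust whole-frame
#'   background estimate, see [background_threshold()]) or a list
#'   `list(rows = c(r1, r2), cols = c(c1, c2))` giving a signal-free
#'   rectangle.
#' @param watershed_sigma_px Gaussian smoothing sigma (pixels) applied
#'   before peak finding in watershed splitting.
#' @param watershed_prominence_sd Peak prominence required to seed a
#'   watershed marker, in units of the background SD.
#' @param exclusion_k_sd Multiplier for the intra-window influx exclusion
#'   rule (excluded when last-frame minus first-frame intensity exceeds
#'   k * background SD).
#' @param seed Optional default seed recorded in run manifests.
#' @return An object of class `analysis_config` (a validated list).
#' @seealso [load_config()]
#' @export
analysis_config <- function(azlm_area_min_um2 = 0.098,
                            azlm_area_max_um2 = 0.38,
                            syp_area_min_um2 = 0.098,
                            threshold_k_sd = 3,
                            ph6_frames_used = 2:5,
                            background_roi = NULL,
                            watershed_sigma_px = 1,
                            watershed_prominence_sd = 1,
                            exclusion_k_sd = 3,
                            seed = NULL) {
  cfg <- list(azlm_area_min_um2 = azlm_area_min_um2,
              azlm_area_max_um2 = azlm_area_max_um2,
              syp_area_min_um2 = syp_area_min_um2,
              threshold_k_sd = threshold_k_sd,
              ph6_frames_used = as.integer(ph6_frames_used),
              background_roi = background_roi,
              watershed_sigma_px = watershed_sigma_px,
              watershed_prominence_sd = watershed_prominence_sd,
              exclusion_k_sd = exclusion_k_sd,
              seed = seed)
  .validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

#' @noRd
.validate_config <- function(cfg) {
  .assert(cfg$azlm_area_min_um2 > 0 &&
            cfg$azlm_area_min_um2 < cfg$azlm_area_max_um2,
          "area gate invalid: need 0 < area_min (%g) < area_max (%g)",
          cfg$azlm_area_min_um2, cfg$azlm_area_max_um2)
  .assert(cfg$syp_area_min_um2 > 0, "syp_area_min_um2 must be > 0")
  .assert(cfg$threshold_k_sd > 0, "threshold_k_sd must be > 0")
  .assert(all(cfg$ph6_frames_used >= 1), "ph6_frames_used must be >= 1")
  .assert(cfg$watershed_sigma_px >= 0, "watershed_sigma_px must be >= 0")
  .assert(cfg$watershed_prominence_sd >= 0,
          "watershed_prominence_sd must be >= 0")
  .assert(cfg$exclusion_k_sd > 0, "exclusion_k_sd must be > 0")
  invisible(cfg)
}

#' Load an analysis configuration from YAML or JSON
#'
#' Unknown keys are rejected (misspelled settings fail loudly rather than
#' silently falling back to defaults); missing keys take the defaults of
#' [analysis_config()]. An empty file yields the full default
#' configuration.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `analysis_config`.
#' @export
load_config <- function(path) {
  .assert(file.exists(path), "config file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  .assert(is.list(raw), "config file must contain a mapping")
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  .assert(length(unknown) == 0, "unknown config keys: %s",
          paste(unknown, collapse = ", "))
  do.call(analysis_config, raw)
}

#' Write an analysis configuration to YAML
#'
#' @param cfg An `analysis_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
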