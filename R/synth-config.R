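#' Optical configuration of the simulated microscope
#'
#' Defaults follow the imaging system being emulated: a 150x NA 1.45 TIRF
#' objective with a 1.6x intermediate lens and a 16 um-pixel EMCCD gives
#' 16000 / 240 = 66.7 nm pixels; the evanescent field decays with a
#' 151 nm length constant; single-SEP brightness is 2900 a.u. at room
#' temperature (21-23 C) and 2200 a.u. at near-physiological temperature
#' (31-32 C) on the instrument's arbitrary scale.
#'
#' @param pixel_size_nm Physical pixel size (nm).
#' @param psf_sigma_nm Gaussian PSF sigma (nm).
#' @param tirf_depth_nm Evanescent-field decay length (nm).
#' @param quench_residual Fraction of surface SEP brightness remaining at
#'   pH 6.0 (0 <= q < 0.1).
#' @param sep_brightness_rt,sep_brightness_pt Single-molecule SEP
#'   intensity (a.u.) at room / near-physiological temperature.
#' @return An `optics_config` list.
#' @export
optics_config <- function(pixel_size_nm = 66.7, psf_sigma_nm = 130,
                          tirf_depth_nm = 151, quench_residual = 0.0,
                          sep_brightness_rt = 2900,
                          sep_brightness_pt = 2200) {
  .assert(pixel_size_nm > 0 && psf_sigma_nm > 0 && tirf_depth_nm > 0,
          "all optical lengths must be > 0")
  .assert(quench_residual >= 0 && quench_residual < 0.1,
          "quench_residual must be in [0, 0.1)")
  .assert(sep_brightness_rt > 0 && sep_brightness_pt > 0,
          "brightness values must be > 0")
  structure(list(pixel_size_nm = pixel_size_nm, psf_sigma_nm = psf_sigma_nm,
                 tirf_depth_nm = tirf_depth_nm,
                 quench_residual = quench_residual,
                 sep_brightness_rt = sep_brightness_rt,
                 sep_brightness_pt = sep_brightness_pt),
            class = "optics_config")
}

#' EMCCD-like noise configuration
#'
#' Shot noise is modeled as Poisson(signal / photon_scale) * photon_scale
#' with EM-gain excess noise folded into `photon_scale`, plus Gaussian
#' read noise and a constant background offset. Set `noise = NULL` in the
#' renderer for noise-free images.
#'
#' @param photon_scale a.u. per expected photon.
#' @param read_noise_sd Gaussian read noise SD (a.u.).
#' @param background_level Constant background offset (a.u.).
#' @return A `noise_config` list.
#' @export
noise_config <- function(photon_scale = 10, read_noise_sd = 10,
                         background_level = 100) {
  .assert(photon_scale > 0, "photon_scale must be > 0")
  .assert(read_noise_sd >= 0, "read_noise_sd must be >= 0")
  .assert(background_level >= 0, "background_level must be >= 0")
  structure(list(photon_scale = photon_scale, read_noise_sd = read_noise_sd,
                 background_level = background_level),
            class = "noise_config")
}

#' Background noise SD implied by a noise configuration
#'
#' SD of a background pixel: sqrt(background * photon_scale +
#' read_noise^2). Used to calibrate simulated contrasts against the
#' mean + k * SD detection threshold.
#'
#' @param noise A [noise_config()], or `NULL` (returns 0).
#' @return Numeric scalar (a.u.).
#' @export
background_noise_sd <- function(noise) {
  if (is.null(noise)) return(0)
  sqrt(noise$background_level * noise$photon_scale + noise$read_noise_sd^2)
}

#' Single exo- or endocytosis ground-truth event
#'
#' @param kind `"exo"` (fusion; fluorophores appear on the surface inside
#'   the AZLM and spread laterally) or `"endo"` (an internalized vesicle
#'   appearing near the AZLM edge at depth `z_nm`).
#' @param mode Endocytosis mode: `"CME"`, `"ADBE"`, `"UFE"`, or `"none"`
#'   (exocytosis).
#' @param t_event Event time in seconds after stimulation onset (>= 0).
#' @param xy_nm Length-2 position (x, y) in nm relative to the AZLM
#'   center.
#' @param z_nm Height above the coverslip (nm, >= 0); surface events use 0.
#' @param amplitude_molecules Number of SEP fluorophores (> 0).
#' @param acidification_tau Re-acidification time constant (s) for endo
#'   events; the vesicle lumen acidifies over 3-15 s, fading its SEP.
#' @param diffusion_sigma_rate Lateral spread rate for exo events
#'   (nm / sqrt(s)): released Syp spreads as a Gaussian of sigma
#'   `rate * sqrt(t - t_event)`.
#' @param surface_decay_tau Time constant (s) with which exocytosed
#'   surface Syp-SEP leaves the evanescent footprint (diffusion out of the
#'   field plus retrieval); governs the pH 7.4 signal decay.
#' @return A `gt_event` list.
#' @export
gt_event <- function(kind = c("exo", "endo"),
                     mode = c("none", "CME", "ADBE", "UFE"),
                     t_event, xy_nm, z_nm = 0, amplitude_molecules,
                     acidification_tau = NA, diffusion_sigma_rate = 150,
                     surface_decay_tau = 20) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  .assert(t_event >= 0, "t_event must be >= 0")
  .assert(length(xy_nm) == 2 && all(is.finite(xy_nm)),
          "xy_nm must be a finite 2-vector")
  .assert(z_nm >= 0, "z_nm must be >= 0")
  .assert(amplitude_molecules > 0, "amplitude_molecules must be > 0")
  if (kind == "endo")
    .assert(!is.na(acidification_tau) && acidification_tau > 0,
            "endo events need a positive acidification_tau")
  structure(list(kind = kind, mode = mode, t_event = t_event,
                 xy_nm = as.numeric(xy_nm), z_nm = z_nm,
                 amplitude_molecules = amplitude_molecules,
                 acidification_tau = acidification_tau,
                 diffusion_sigma_rate = diffusion_sigma_rate,
                 surface_decay_tau = surface_decay_tau),
            class = "gt_event")
}

#' Assemble a full ground-truth description of one simulated recording
#'
#' @param events List of [gt_event()]s.
#' @param azlm_radius_nm AZLM disc radius (nm). The disc area must fall
#'   inside the 0.098-0.38 um^2 gate used by the analysis.
#' @param azlm_center_nm Disc center offset (x, y) in nm from the field
#'   center.
#' @param drift_nm_per_s Stage drift velocity (x, y) in nm/s.
#' @param bleach A [bleach_model()] applied to the SEP channel.
#' @param exchange_down_ms,exchange_up_ms 10-90% solution-exchange times
#'   (ms) of the U-tube pH switch (7.4 -> 6.0 and back).
#' @param temperature_C Bath temperature.
#' @param cast_peak CAST channel disc amplitude (a.u.); `NULL` defers to
#'   the render-time calibration of [cast_amplitude_for_gate()].
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(events = list(), azlm_radius_nm = 252.3,
                         azlm_center_nm = c(0, 0),
                         drift_nm_per_s = c(0, 0),
                         bleach = bleach_model(1, Inf),
                         exchange_down_ms = 100, exchange_up_ms = 200,
                         temperature_C = 22, cast_peak = NULL) {
  area_um2 <- pi * azlm_radius_nm^2 / 1e6
  .assert(area_um2 >= 0.098 && area_um2 <= 0.38,
          "AZLM disc area %.3f um^2 outside the [0.098, 0.38] gate",
          area_um2)
  .assert(exchange_down_ms > 0 && exchange_up_ms > 0,
          "exchange times must be > 0")
  stopifnot(all(vapply(events, inherits, logical(1), "gt_event")))
  structure(list(events = events, azlm_radius_nm = azlm_radius_nm,
                 azlm_center_nm = as.numeric(azlm_center_nm),
                 drift_nm_per_s = as.numeric(drift_nm_per_s),
                 bleach = bleach, exchange_down_ms = exchange_down_ms,
                 exchange_up_ms = exchange_up_ms,
                 temperature_C = temperature_C, cast_peak = cast_peak),
            class = "ground_truth")
}

#' Ground-truth event list as a data frame
#'
#' @param gt A [ground_truth()].
#' @return One row per event with the [gt_event()] fields.
#' @export
gt_events_df <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  if (!length(gt$events))
    return(data.frame(kind = character(0), mode = character(0),
                      t_event = numeric(0), x_nm = numeric(0),
                      y_nm = numeric(0), z_nm = numeric(0),
                      amplitude_molecules = numeric(0),
                      acidification_tau = numeric(0)))
  do.call(rbind, lapply(gt$events, function(e)
    data.frame(kind = e$kind, mode = e$mode, t_event = e$t_event,
               x_nm = e$xy_nm[1], y_nm = e$xy_nm[2], z_nm = e$z_nm,
               amplitude_molecules = e$amplitude_molecules,
               acidification_tau = e$acidification_tau)))
}
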