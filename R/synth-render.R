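# Forward model: ground truth -> pixel data.
#
# Point emitters are rendered as pixel-integrated 2-D Gaussians (exact
# separable integral of the PSF over each pixel), so the summed intensity
# of an unclipped blob equals its amplitude exactly. The AZLM disc uses
# the closed form for a uniform disc convolved with a Gaussian: at radial
# distance rho from the disc center the value is
# P(|Z + rho| <= r0) = pchisq(r0^2/sigma^2, df = 2, ncp = rho^2/sigma^2),
# Z ~ N(0, sigma^2 I2).

#' CAST disc amplitude matched to the detection threshold
#'
#' The analysis defines the AZLM as the supra-threshold CAST area at
#' threshold = background mean + k * SD, so the *detected* disc size
#' depends on the rendered contrast. Edge distances are measured to the
#' centers of the outermost supra-threshold pixels; at a given angle the
#' outermost pixel center falls uniformly within one pixel inside the
#' threshold contour, and the minimum over the boundary pixels spanning
#' the nearest angular neighbourhood sits about a quarter pixel inside
#' it in expectation. This helper therefore returns the amplitude at
#' which the threshold contour of the PSF-blurred disc lies a quarter
#' pixel outside the nominal disc edge, so that distances measured to
#' the detected boundary-pixel centers estimate distances to the
#' nominal edge without systematic offset. With no noise a nominal
#' fallback contrast is returned.
#'
#' @param noise A [noise_config()] or `NULL`.
#' @param optics An [optics_config()].
#' @param azlm_radius_nm Nominal disc radius (nm).
#' @param k_sd Threshold multiplier the analysis will use (default 3).
#' @return Disc plateau amplitude in a.u.
#' @export
cast_amplitude_for_gate <- function(noise, optics, azlm_radius_nm = 252.3,
                                    k_sd = 3) {
  sd_bg <- background_noise_sd(noise)
  if (sd_bg <= 0) return(1000)
  s <- optics$psf_sigma_nm
  r_contour <- azlm_radius_nm + optics$pixel_size_nm / 4
  edge_val <- stats::pchisq((azlm_radius_nm / s)^2, df = 2,
                            ncp = (r_contour / s)^2)
  k_sd * sd_bg / edge_val
}

#' @noRd
.disc_profile <- function(rho_nm, radius_nm, sigma_nm) {
  stats::pchisq((radius_nm / sigma_nm)^2, df = 2,
                ncp = (rho_nm / sigma_nm)^2)
}

#' Render one channel of a simulated acquisition
#'
#' Per frame, each fluorophore contributes
#' `molecules x brightness x exp(-z / tirf_depth) x pH factor x bleach
#' factor`, placed as a Gaussian blob (PSF sigma, widened by lateral
#' diffusion for surface Syp after fusion). Surface-exposed fluorophores
#' are quenched to `quench_residual` while the extracellular pH is 6.0;
#' endocytosed vesicles are insensitive to the bath pH but fade as their
#' lumen re-acidifies (`exp(-(t - t_event) / acidification_tau)`).
#' Stage drift translates everything; the CAST channel renders only the
#' static (drifting) AZLM disc, unbleached. Single-SEP brightness follows
#' the bath temperature (RT below 30 C, PT above).
#'
#' @param gt A [ground_truth()]; event times are seconds after
#'   stimulation onset (or absolute when the timeline has none).
#' @param timeline An [make_timeline()] object.
#' @param optics An [optics_config()].
#' @param noise A [noise_config()]; its `background_level` is always
#'   added, the stochastic parts only when `apply_noise = TRUE`.
#' @param channel `"SEP"` or `"CAST"`.
#' @param seed Optional RNG seed (noise only).
#' @param dim_px Field size `c(ny, nx)` in pixels.
#' @param apply_noise Add Poisson shot noise and Gaussian read noise.
#' @return A [frame_stack()].
#' @export
render_stack <- function(gt, timeline, optics = optics_config(),
                         noise = noise_config(),
                         channel = c("SEP", "CAST"), seed = NULL,
                         dim_px = c(64, 64), apply_noise = TRUE) {
  channel <- match.arg(channel)
  stopifnot(inherits(gt, "ground_truth"), inherits(timeline, "acq_timeline"))
  ny <- dim_px[1]; nx <- dim_px[2]
  px <- optics$pixel_size_nm
  xs <- .px_centers_nm(nx, px)
  ys <- .px_centers_nm(ny, px)
  center <- c(mean(range(xs)), mean(range(ys))) + gt$azlm_center_nm
  t0_off <- if (is.na(timeline$stim_onset)) 0 else timeline$stim_onset
  bright <- if (gt$temperature_C >= 30) optics$sep_brightness_pt else
    optics$sep_brightness_rt
  cast_peak <- gt$cast_peak %||%
    cast_amplitude_for_gate(noise, optics, gt$azlm_radius_nm)
  bg <- if (is.null(noise)) 0 else noise$background_level

  stack <- array(0, dim = c(ny, nx, n_frames(timeline)))
  for (fi in seq_len(n_frames(timeline))) {
    t <- timeline$frame_times[fi]
    drift <- gt$drift_nm_per_s * t
    clean <- matrix(0, ny, nx)
    if (channel == "CAST") {
      cx <- center[1] + drift[1]; cy <- center[2] + drift[2]
      rho <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
      clean <- cast_peak * .disc_profile(rho, gt$azlm_radius_nm,
                                         optics$psf_sigma_nm)
    } else {
      ph6 <- timeline$frame_ph[fi] == 6.0
      bfac <- bleach_factor(gt$bleach, t)
      for (e in gt$events) {
        te <- e$t_event + t0_off
        if (t < te) next
        pos <- center + e$xy_nm + drift
        if (e$kind == "exo") {
          sig <- sqrt(optics$psf_sigma_nm^2 +
                        e$diffusion_sigma_rate^2 * (t - te))
          amp <- e$amplitude_molecules * bright * bfac *
            exp(-(t - te) / e$surface_decay_tau) *
            (if (ph6) optics$quench_residual else 1)
        } else {
          sig <- optics$psf_sigma_nm
          amp <- e$amplitude_molecules * bright * bfac *
            exp(-e$z_nm / optics$tirf_depth_nm) *
            exp(-(t - te) / e$acidification_tau)
        }
        if (amp <= 0) next
        gx <- .pixel_gauss(xs, pos[1], sig, px)
        gy <- .pixel_gauss(ys, pos[2], sig, px)
        clean <- clean + amp * outer(gy, gx)
      }
    }
    stack[, , fi] <- clean + bg
  }

  if (apply_noise && !is.null(noise)) {
    stack <- .with_seed(seed, {
      n <- length(stack)
      shot <- stats::rpois(n, pmax(stack, 0) / noise$photon_scale) *
        noise$photon_scale
      read <- if (noise$read_noise_sd > 0)
        stats::rnorm(n, 0, noise$read_noise_sd) else 0
      array(shot + read, dim = dim(stack))
    })
  }
  frame_stack(stack, channel = channel, pixel_size_nm = px,
              timeline = timeline)
}
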