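# Internal helpers shared across modules.

# Tolerance used when assigning frames to pH windows; guards against
# floating-point jitter in frame-time grids (e.g. 25 * 0.12 != 3 exactly).
.time_eps <- 1e-9

#' @noRd
.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# Run `expr` under a fixed RNG seed when `seed` is given; leaves the
# caller's RNG state untouched either way.
#' @noRd
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  .assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
          "seed must be a single finite number")
  withr::with_seed(as.integer(seed), expr)
}

# Physical coordinate of pixel centers along one axis (1-based index
# `i` maps to (i - 1) * pixel_size_nm).
#' @noRd
.px_centers_nm <- function(n, pixel_size_nm) (seq_len(n) - 1) * pixel_size_nm

# Pixel-integrated 1-D Gaussian: integral of N(mu, sigma^2) over each
# pixel [c - px/2, c + px/2]. Returns a vector summing to ~1 when the
# support lies inside the field.
#' @noRd
.pixel_gauss <- function(centers_nm, mu_nm, sigma_nm, pixel_size_nm) {
  h <- pixel_size_nm / 2
  stats::pnorm((centers_nm + h - mu_nm) / sigma_nm) -
    stats::pnorm((centers_nm - h - mu_nm) / sigma_nm)
}
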