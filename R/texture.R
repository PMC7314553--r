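#' Generate a random background texture pattern
#'
#' Draws i.i.d. Gaussian pixel intensities (8-bit units), clips to [0, 255],
#' and smooths with a uniform box filter. The granularity of the texture is
#' set by the kernel size and the Gaussian width. Clipping is applied before
#' filtering by default; `clip = "post"` filters the raw draw and clips the
#' result instead.
#'
#' @param shape_px c(height, width) in pixels
#' @param gauss_mean Gaussian mean, 8-bit units (default 40)
#' @param gauss_sd Gaussian SD, 8-bit units (default 60)
#' @param kernel_px side of the uniform box kernel (default 6)
#' @param clip "pre" (default) or "post" filtering
#' @param seed integer seed
#' @return numeric matrix of pixel intensities in [0, 255]
#' @export
generate_texture <- function(shape_px = c(256, 256), gauss_mean = 40,
                             gauss_sd = 60, kernel_px = 6, clip = "pre",
                             seed = 1) {
  stopifnot(kernel_px >= 1, all(shape_px >= 1))
  clip <- match.arg(clip, c("pre", "post"))
  rng <- local_rng(seed)
  on.exit(rng())
  img <- matrix(stats::rnorm(prod(shape_px), gauss_mean, gauss_sd),
                shape_px[1], shape_px[2])
  clip01 <- function(m) pmin(pmax(m, 0), 255)
  if (clip == "pre") img <- clip01(img)
  img <- box_filter(img, kernel_px)
  if (clip == "post") img <- clip01(img)
  img
}

# Uniform (box) mean filter, separable; edges use the truncated-window mean
# so a constant image stays constant. kernel 1 is the identity.
box_filter <- function(img, k) {
  if (k == 1) return(img)
  run_mean <- function(v) {
    n <- length(v)
    half_lo <- floor((k - 1) / 2)
    half_hi <- k - 1 - half_lo
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - half_lo, 1)
    hi <- pmin(seq_len(n) + half_hi, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  t(apply(apply(img, 2, run_mean), 1, run_mean))
}

#' Display pixel-to-luminance calibration
#'
#' Fixed cubic calibration of the projection system mapping pixel intensity
#' x (PsychoPy convention, range -1 to 1) to luminance in cd/m^2:
#' y = -78.8 x^3 + 78.7 x^2 + 317.2 x + 163.3. Values outside [-1, 1] are
#' still evaluated but flagged with a warning.
#'
#' @param x pixel intensity, PsychoPy units
#' @return luminance, cd/m^2
#' @export
pixel_to_luminance <- function(x) {
  if (any(x < -1 | x > 1))
    warning("pixel intensity outside [-1, 1]; extrapolating the calibration")
  -78.8 * x^3 + 78.7 * x^2 + 317.2 * x + 163.3
}
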