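#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities, h(t) = g(t; a1, b1) - ratio * g(t; a2,
#' b2), sampled at the TR and peak-normalised to 1. Defaults are the canonical
#' values: response peak 6 s, undershoot peak 16 s, unit dispersions,
#' undershoot ratio 1/6.
#'
#' @param peak_delay_s time-to-peak of the positive response, s (default 6)
#' @param undershoot_delay_s time-to-peak of the undershoot, s (default 16)
#' @param peak_disp dispersion of the positive gamma (default 1)
#' @param undershoot_disp dispersion of the undershoot gamma (default 1)
#' @param ratio undershoot amplitude ratio (default 1/6)
#' @param length_s kernel length, s (default 32)
#' @param tr sampling interval, s
#' @return numeric kernel sampled at `0, tr, 2*tr, ...`, peak 1
#' @export
double_gamma_hrf <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                             peak_disp = 1, undershoot_disp = 1,
                             ratio = 1 / 6, length_s = 32, tr = 2.079) {
  if (tr <= 0) stop("TR must be positive")
  if (peak_disp <= 0 || undershoot_disp <= 0)
    stop("dispersions must be positive")
  t <- seq(0, length_s, by = tr)
  h <- hrf_shape(t, peak_delay_s, undershoot_delay_s, peak_disp,
                 undershoot_disp, ratio)
  structure(h / max(h),
            hrf_params = list(peak_delay_s = peak_delay_s,
                              undershoot_delay_s = undershoot_delay_s,
                              peak_disp = peak_disp,
                              undershoot_disp = undershoot_disp,
                              ratio = ratio))
}

# continuous double-gamma evaluated at arbitrary times (gamma-density
# parameterisation: shape = delay/dispersion, scale = dispersion)
hrf_shape <- function(t, peak_delay_s = 6, undershoot_delay_s = 16,
                      peak_disp = 1, undershoot_disp = 1, ratio = 1 / 6) {
  stats::dgamma(t, shape = peak_delay_s / peak_disp, scale = peak_disp) -
    ratio * stats::dgamma(t, shape = undershoot_delay_s / undershoot_disp,
                          scale = undershoot_disp)
}

# Convolve a set of boxcars (onsets/durations in seconds) with an HRF kernel
# sampled at `tr`, on a fine time grid, and sample at volume onsets.
# Returns a length-n_volumes predictor. `dt` is the quadrature step.
convolve_boxcar <- function(onsets, durations, hrf_tr, tr, n_volumes,
                            dt = tr / 20) {
  total <- n_volumes * tr
  tfine <- seq(0, total - dt, by = dt)
  box <- rep(0, length(tfine))
  for (i in seq_along(onsets)) {
    idx <- tfine >= onsets[i] & tfine < onsets[i] + durations[i]
    box[idx] <- 1
  }
  hfine <- hrf_shape_from_kernel(hrf_tr, tr, dt)
  conv <- stats::convolve(box, rev(hfine), type = "open")[seq_along(tfine)] * dt
  conv[pmin(length(tfine), round(seq(0, n_volumes - 1) * tr / dt) + 1)]
}

# Convolve unit impulses (delta functions at given onset times) with the HRF;
# impulses have unit area so the predictor peaks near the HRF peak value.
convolve_delta <- function(onsets, hrf_tr, tr, n_volumes, dt = tr / 20) {
  total <- n_volumes * tr
  tfine <- seq(0, total - dt, by = dt)
  imp <- rep(0, length(tfine))
  idx <- pmin(length(tfine), round(onsets / dt) + 1)
  for (i in idx) imp[i] <- imp[i] + 1 / dt   # unit-area impulse
  hfine <- hrf_shape_from_kernel(hrf_tr, tr, dt)
  conv <- stats::convolve(imp, rev(hfine), type = "open")[seq_along(tfine)] * dt
  conv[pmin(length(tfine), round(seq(0, n_volumes - 1) * tr / dt) + 1)]
}

# Re-evaluate the continuous canonical shape on a fine grid, normalised so
# that its peak matches the supplied TR-sampled kernel's peak (1 after
# double_gamma_hrf). Custom kernels are linearly interpolated instead.
hrf_shape_from_kernel <- function(hrf_tr, tr, dt) {
  attr_par <- attr(hrf_tr, "hrf_params")
  tfine <- seq(0, (length(hrf_tr) - 1) * tr, by = dt)
  if (!is.null(attr_par)) {
    h <- do.call(hrf_shape, c(list(t = tfine), attr_par))
    return(h / max(h))
  }
  # default canonical parameters reproduce double_gamma_hrf defaults; fall
  # back to interpolation only if the kernel does not match them
  h <- hrf_shape(tfine)
  h <- h / max(h)
  samp <- h[round(seq(0, length(hrf_tr) - 1) * tr / dt) + 1]
  if (max(abs(samp - hrf_tr)) < 1e-6) h
  else stats::approx(seq(0, by = tr, length.out = length(hrf_tr)), hrf_tr,
                     xout = tfine, rule = 2)$y
}

#' Discrete-cosine high-pass filter basis
#'
#' DCT drift basis spanning fluctuations slower than `cutoff_s`, plus the
#' constant term. Used as a projection: high-pass filtering removes the
#' component of a signal lying in this basis, which makes the filter an exact
#' idempotent projector.
#'
#' @param n_volumes number of time points
#' @param tr sampling interval, s
#' @param cutoff_s high-pass cutoff period, s (default 35)
#' @return matrix n_volumes x K of basis regressors (first column constant)
#' @export
dct_highpass_basis <- function(n_volumes, tr, cutoff_s = 35) {
  stopifnot(cutoff_s > 2 * tr)
  total <- n_volumes * tr
  k_max <- floor(2 * total / cutoff_s)
  t <- seq_len(n_volumes) - 0.5
  basis <- matrix(1 / sqrt(n_volumes), n_volumes, k_max + 1)
  for (k in seq_len(k_max))
    basis[, k + 1] <- sqrt(2 / n_volumes) * cos(pi * k * t / n_volumes)
  basis
}

#' Apply the DCT high-pass filter to a vector or columns of a matrix
#'
#' Removes the projection onto the slow-drift DCT basis (including the mean).
#' Applying it twice equals applying it once.
#'
#' @param x numeric vector or matrix (time in rows)
#' @param tr sampling interval, s
#' @param cutoff_s cutoff period, s
#' @return filtered object of the same shape
#' @export
highpass_filter <- function(x, tr, cutoff_s = 35) {
  v <- is.null(dim(x))
  xm <- if (v) matrix(x, ncol = 1) else x
  basis <- dct_highpass_basis(nrow(xm), tr, cutoff_s)
  res <- xm - basis %*% crossprod(basis, xm)   # orthonormal basis projection
  if (v) drop(res) else res
}
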