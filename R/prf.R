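#' Population receptive field model
#'
#' A 2D isotropic Gaussian pRF with centre (x0, y0) and width sigma (standard
#' deviation), all in degrees of visual angle, plus a free response amplitude
#' and the goodness of fit R^2.
#'
#' @param x0,y0 pRF centre, deg
#' @param sigma pRF width (SD), deg; must be positive
#' @param amplitude response amplitude (signal units); NA if unfitted
#' @param r_squared fraction of variance explained; NA for degenerate fits
#' @return an object of class `prf_model`
#' @export
prf_model <- function(x0, y0, sigma, amplitude = NA_real_,
                      r_squared = NA_real_) {
  if (sigma <= 0) stop("pRF sigma must be positive")
  structure(list(x0 = x0, y0 = y0, sigma = sigma, amplitude = amplitude,
                 r_squared = r_squared),
            class = "prf_model")
}

#' @export
print.prf_model <- function(x, ...) {
  cat(sprintf("prf_model: centre (%.3g, %.3g) deg, sigma %.3g deg, R2 %.3f\n",
              x$x0, x$y0, x$sigma, x$r_squared))
  invisible(x)
}

# Gaussian pRF evaluated on the aperture grid; returns a matrix matching one
# aperture frame (rows = +y top to bottom, cols = x left to right).
prf_field <- function(x0, y0, sigma, n_px, deg_per_pixel) {
  xy <- pixel_coords(n_px, deg_per_pixel)
  gx <- exp(-(xy - x0)^2 / (2 * sigma^2))
  gy <- exp(-(rev(xy) - y0)^2 / (2 * sigma^2))
  outer(gy, gx)
}

# Per-volume aperture occupancy. `volume_frames` gives, for each volume, the
# index of the movie frame shown during it (0 = rest / blank). Returns an
# n_volumes x n_pixels matrix.
aperture_by_volume <- function(movie, volume_frames) {
  d <- dim(movie$frames)
  flat <- matrix(movie$frames, d[1], d[2] * d[3])
  out <- matrix(0, length(volume_frames), d[2] * d[3])
  ok <- volume_frames > 0
  out[ok, ] <- flat[volume_frames[ok], , drop = FALSE]
  out
}

#' Predicted pRF time course for an aperture movie
#'
#' Per volume, the spatial overlap between the aperture and the Gaussian pRF
#' (sum over pixels of aperture x Gaussian), convolved with the HRF. The
#' amplitude is left free (the prediction is in arbitrary units).
#'
#' @param prf a [prf_model()]
#' @param movie an [aperture_movie]
#' @param volume_frames integer vector: the movie frame shown during each
#'   volume, 0 for rest (default: one frame per volume, in order)
#' @param hrf HRF kernel (default canonical at `tr`)
#' @param tr repetition time, s
#' @return numeric vector, one value per volume
#' @export
prf_predicted_timecourse <- function(prf, movie, volume_frames = NULL,
                                     hrf = NULL, tr = 2.079) {
  if (prf$sigma <= 0) stop("pRF sigma must be positive")
  d <- dim(movie$frames)
  if (is.null(volume_frames)) volume_frames <- seq_len(d[1])
  if (is.null(hrf)) hrf <- double_gamma_hrf(tr = tr)
  ap <- aperture_by_volume(movie, volume_frames)
  g <- as.vector(prf_field(prf$x0, prf$y0, prf$sigma, d[2],
                           movie$deg_per_pixel))
  overlap <- as.vector(ap %*% g)
  convolve_neural(overlap, hrf)
}

# discrete convolution of a per-volume neural series with a TR-sampled kernel
convolve_neural <- function(x, kernel) {
  n <- length(x)
  stats::convolve(x, rev(kernel), type = "open")[seq_len(n)]
}

#' Candidate grid for pRF fitting
#'
#' @param x,y candidate centre coordinates, deg
#' @param sigma candidate widths, deg (log-spaced by default)
#' @return data.frame of all candidate (x0, y0, sigma) triples
#' @export
prf_grid_spec <- function(x = seq(-4, 4, by = 0.25),
                          y = seq(-4, 4, by = 0.25),
                          sigma = exp(seq(log(0.2), log(2), length.out = 6))) {
  stopifnot(length(x) > 0, length(y) > 0, all(sigma > 0))
  expand.grid(x0 = x, y0 = y, sigma = sigma, KEEP.OUT.ATTRS = FALSE)
}

#' Precompute predicted time courses for a candidate grid
#'
#' Heavy lifting for [fit_prf_grid()]: overlap of every candidate Gaussian
#' with the per-volume aperture, HRF-convolved, mean-centred and
#' norm-scaled. Compute once, reuse across units.
#'
#' @inheritParams prf_predicted_timecourse
#' @param grid a [prf_grid_spec()] data.frame
#' @return list with `grid`, `pred` (n_volumes x n_candidates, centred
#'   unit-norm), `pred_raw`, and the call geometry
#' @export
prf_candidate_predictions <- function(grid, movie, volume_frames = NULL,
                                      hrf = NULL, tr = 2.079) {
  d <- dim(movie$frames)
  if (is.null(volume_frames)) volume_frames <- seq_len(d[1])
  n_volumes <- length(volume_frames)
  if (is.null(hrf)) hrf <- double_gamma_hrf(tr = tr)
  ap <- aperture_by_volume(movie, volume_frames)             # vol x px
  xy <- pixel_coords(d[2], movie$deg_per_pixel)
  # Gaussian separable over the pixel grid: build n_px x n_cand factors
  n_cand <- nrow(grid)
  G <- matrix(0, d[2] * d[3], n_cand)
  for (j in seq_len(n_cand))
    G[, j] <- as.vector(prf_field(grid$x0[j], grid$y0[j], grid$sigma[j],
                                  d[2], movie$deg_per_pixel))
  overlap <- ap %*% G                                        # vol x cand
  # convolve all candidates with the kernel via FFT on columns
  pred <- apply(overlap, 2, convolve_neural, kernel = hrf)
  pred_c <- sweep(pred, 2, colMeans(pred))
  nrm <- sqrt(colSums(pred_c^2))
  ok <- nrm > 1e-12
  pred_c[, ok] <- sweep(pred_c[, ok, drop = FALSE], 2, nrm[ok], "/")
  list(grid = grid, pred = pred_c, pred_scale = nrm, valid = ok,
       pred_raw = pred, n_volumes = n_volumes)
}

#' Fit pRF models by exhaustive grid search
#'
#' For each time course, the candidate maximising R^2 (amplitude by least
#' squares with intercept) is selected; ties are broken toward smaller sigma,
#' then smaller eccentricity. Zero-variance time courses are flagged as
#' degenerate (NA R^2, no model).
#'
#' @param timecourses vector or matrix (time x units)
#' @param candidates a [prf_candidate_predictions()] result
#' @return data.frame: x0, y0, sigma, amplitude, r_squared (one row per unit)
#' @export
fit_prf_grid <- function(timecourses, candidates) {
  Y <- if (is.null(dim(timecourses))) matrix(timecourses, ncol = 1) else
    timecourses
  stopifnot(nrow(Y) == candidates$n_volumes)
  Yc <- sweep(Y, 2, colMeans(Y))
  ss_tot <- colSums(Yc^2)
  grid <- candidates$grid
  P <- candidates$pred[, candidates$valid, drop = FALSE]
  gidx <- which(candidates$valid)
  # correlation with unit-norm predictors: R^2 = (P'y)^2 / ss_tot
  proj <- crossprod(P, Yc)                      # cand x units
  out <- data.frame(x0 = rep(NA_real_, ncol(Y)), y0 = NA_real_,
                    sigma = NA_real_, amplitude = NA_real_,
                    r_squared = NA_real_)
  ecc <- sqrt(grid$x0^2 + grid$y0^2)
  for (j in seq_len(ncol(Y))) {
    if (ss_tot[j] < 1e-12) next                 # degenerate: flat time course
    r2 <- proj[, j]^2 / ss_tot[j]
    best <- max(r2)
    cand <- which(r2 >= best - 1e-12)
    gi <- gidx[cand]
    ord <- order(grid$sigma[gi], ecc[gi])
    pick <- cand[ord[1]]
    gp <- gidx[pick]
    out$x0[j] <- grid$x0[gp]
    out$y0[j] <- grid$y0[gp]
    out$sigma[j] <- grid$sigma[gp]
    out$amplitude[j] <- proj[pick, j] / candidates$pred_scale[gp]
    out$r_squared[j] <- r2[pick]
  }
  out
}

#' Eccentricity and polar-angle maps from fitted pRFs
#'
#' @param prf_map data.frame with columns x0, y0 (from [fit_prf_grid()])
#' @return data.frame with `eccentricity_deg` and `polar_angle_deg`
#'   (counter-clockwise from the positive x-axis); NA fits propagate
#' @export
derive_retinotopy <- function(prf_map) {
  data.frame(eccentricity_deg = sqrt(prf_map$x0^2 + prf_map$y0^2),
             polar_angle_deg = atan2(prf_map$y0, prf_map$x0) * 180 / pi)
}
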