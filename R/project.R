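#' Visual-field grid specification
#'
#' @param extent_deg half-extent of the square grid, deg (default 4.25,
#'   covering the 3.75 deg stimulus radius with margin)
#' @param deg_per_pixel resolution (default 0.05)
#' @return list with pixel-centre coordinate vectors `x` (rightward) and `y`
#'   (upward, top row first) and the geometry
#' @export
visual_field_grid <- function(extent_deg = 4.25, deg_per_pixel = 0.05) {
  stopifnot(extent_deg > 0, deg_per_pixel > 0)
  n_px <- round(2 * extent_deg / deg_per_pixel)
  xy <- pixel_coords(n_px, deg_per_pixel)
  list(x = xy, y = rev(xy), n_px = n_px, extent_deg = extent_deg,
       deg_per_pixel = deg_per_pixel)
}

#' Project unit statistics into the visual field
#'
#' Each unit k contributes its statistic p_k weighted by its Gaussian pRF
#' evaluated over the grid, M_ijk = exp(-((x_i - x_k)^2 + (y_j - y_k)^2) /
#' (2 sigma_k^2)); the projection is the pRF-density-normalised weighted
#' mean V = sum_k M_k p_k / sum_k M_k, element-wise, with no smoothing.
#' Pixels where the density sum falls below `density_floor` times the peak
#' density are masked (NA in `V_masked`).
#'
#' @param prf_map data.frame with columns x0, y0, sigma (one row per unit)
#' @param psc numeric vector, one statistic (e.g. percent signal change)
#'   per unit
#' @param grid a [visual_field_grid()]
#' @param density_floor mask fraction of peak density (default 0.01)
#' @return a `visual_field_projection` list: `V`, `density`, `mask`,
#'   `V_masked`, `grid`
#' @export
project_to_visual_field <- function(prf_map, psc, grid = visual_field_grid(),
                                    density_floor = 0.01) {
  n <- nrow(prf_map)
  if (is.null(n) || n == 0) stop("empty pRF model set")
  stopifnot(length(psc) == n, all(prf_map$sigma > 0))
  num <- matrix(0, grid$n_px, grid$n_px)
  den <- matrix(0, grid$n_px, grid$n_px)
  for (k in seq_len(n)) {
    gx <- exp(-(grid$x - prf_map$x0[k])^2 / (2 * prf_map$sigma[k]^2))
    gy <- exp(-(grid$y - prf_map$y0[k])^2 / (2 * prf_map$sigma[k]^2))
    M <- outer(gy, gx)
    num <- num + M * psc[k]
    den <- den + M
  }
  V <- num / den
  mask <- den >= density_floor * max(den)
  Vm <- V
  Vm[!mask] <- NA_real_
  structure(list(V = V, density = den, mask = mask, V_masked = Vm,
                 grid = grid, density_floor = density_floor),
            class = "visual_field_projection")
}

#' @export
print.visual_field_projection <- function(x, ...) {
  cat(sprintf(
    "visual_field_projection: %dx%d px, %.0f%% unmasked, range [%.3g, %.3g]\n",
    nrow(x$V), ncol(x$V), 100 * mean(x$mask),
    min(x$V_masked, na.rm = TRUE), max(x$V_masked, na.rm = TRUE)))
  invisible(x)
}

#' Pool subjects into one visual-field projection
#'
#' Concatenates all subjects' (pRF model, statistic) pairs before the density
#' normalisation — a single projection over the pooled unit set, not an
#' average of per-subject projections.
#'
#' @param prf_maps list of per-subject pRF data.frames
#' @param psc_list list of per-subject statistic vectors
#' @param grid a [visual_field_grid()] (shared across subjects)
#' @param density_floor mask fraction of peak density
#' @return a `visual_field_projection`
#' @export
pool_projections <- function(prf_maps, psc_list, grid = visual_field_grid(),
                             density_floor = 0.01) {
  stopifnot(length(prf_maps) == length(psc_list), length(prf_maps) >= 1)
  prf <- do.call(rbind, lapply(prf_maps, function(m)
    m[, c("x0", "y0", "sigma")]))
  psc <- unlist(psc_list, use.names = FALSE)
  project_to_visual_field(prf, psc, grid, density_floor)
}
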