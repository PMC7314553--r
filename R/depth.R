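#' Equi-volume cortical depth levels
#'
#' Places `n_compartments` depth compartments between the pial surface and
#' the white/grey-matter boundary so that each compartment encloses equal
#' tissue volume, yielding `n_compartments + 1` boundary depth fractions.
#' Depth convention: fraction 0 = pial surface, 1 = white-matter boundary.
#'
#' Supported geometries per column:
#' \describe{
#'   \item{flat}{no curvature; equal volume reduces to equidistant fractions.}
#'   \item{annular}{cortex as a 2D annulus between `r_wm` (inner) and
#'     `r_pial` (outer): boundary radii satisfy
#'     r_j = sqrt(r_wm^2 + (j/n)(r_pial^2 - r_wm^2)).}
#'   \item{spherical}{3D shell: r_j = (r_wm^3 + (j/n)(r_pial^3 - r_wm^3))^(1/3).}
#' }
#'
#' @param n_compartments number of equal-volume compartments (default 10)
#' @param geometry "flat", "annular" or "spherical"
#' @param r_pial,r_wm outer (pial) and inner (white-matter) radii for curved
#'   geometries; require `r_pial > r_wm > 0`
#' @return a `depth_levels` list: `fractions` (length n+1, increasing, 0 to
#'   1), `n_compartments`, `geometry`, and the radii for curved geometries
#' @export
equivolume_boundaries <- function(n_compartments = 10, geometry = "flat",
                                  r_pial = NULL, r_wm = NULL) {
  stopifnot(n_compartments >= 1)
  geometry <- match.arg(geometry, c("flat", "annular", "spherical"))
  j <- seq(0, n_compartments)
  if (geometry == "flat") {
    fr <- j / n_compartments
  } else {
    if (is.null(r_pial) || is.null(r_wm) || !(r_pial > r_wm && r_wm > 0))
      stop("curved geometry requires r_pial > r_wm > 0")
    p <- if (geometry == "annular") 2 else 3
    r <- (r_wm^p + (j / n_compartments) * (r_pial^p - r_wm^p))^(1 / p)
    fr <- rev((r_pial - r) / (r_pial - r_wm))   # depth measured from pial
  }
  structure(list(fractions = fr, n_compartments = n_compartments,
                 geometry = geometry, r_pial = r_pial, r_wm = r_wm),
            class = "depth_levels")
}

#' @export
print.depth_levels <- function(x, ...) {
  cat(sprintf("depth_levels: %d compartments (%s), %d boundaries\n",
              x$n_compartments, x$geometry, length(x$fractions)))
  invisible(x)
}

#' Sample a statistic across cortical depth
#'
#' Interpolates a per-column statistic, defined on a native depth grid, at
#' the equi-volume boundary fractions (linear interpolation along depth — the
#' depth axis of a trilinear scheme on the lattice geometry used here).
#'
#' @param statistic_map matrix columns x native-depth samples
#' @param native_fractions depth fractions (0 = pial) of the native samples
#' @param depth_levels an [equivolume_boundaries()] result
#' @return matrix columns x boundaries of interpolated values
#' @export
sample_across_depth <- function(statistic_map, native_fractions,
                                depth_levels) {
  M <- as.matrix(statistic_map)
  stopifnot(ncol(M) == length(native_fractions))
  out <- t(apply(M, 1, function(v)
    stats::approx(native_fractions, v, xout = depth_levels$fractions,
                  rule = 2)$y))
  colnames(out) <- sprintf("depth_%.3f", depth_levels$fractions)
  out
}

#' Quantitative ROI selection over cortical columns
#'
#' A cortical column (segment) is included iff all three criteria hold:
#' \enumerate{
#'   \item median over depths of the pRF R^2 exceeds `r2_threshold`;
#'   \item minimum over depths of the mean-EPI intensity is at least
#'     `intensity_threshold` (vein/sinus exclusion);
#'   \item median eccentricity over depths falls in the requested band
#'     (centre: 1 to 3 deg; edge: 3.5 to 4.0 deg).
#' }
#' Selection is all-or-none per column: either every depth of a segment is in
#' the ROI or none is.
#'
#' @param r2 matrix columns x depths of pRF R^2
#' @param epi_intensity matrix columns x depths of mean-EPI intensity
#' @param eccentricity matrix columns x depths of pRF eccentricity (deg)
#' @param band "centre" or "edge", or a length-2 numeric band (deg)
#' @param r2_threshold default 0.15
#' @param intensity_threshold default 7000
#' @param area optional character vector of column area labels; with
#'   `areas`, restricts to those labels
#' @param areas area labels to keep (default all)
#' @return a `roi_selection` list: `included` (logical per column), `band`,
#'   `criteria`
#' @export
select_roi <- function(r2, epi_intensity, eccentricity, band = "centre",
                       r2_threshold = 0.15, intensity_threshold = 7000,
                       area = NULL, areas = NULL) {
  r2 <- as.matrix(r2); epi_intensity <- as.matrix(epi_intensity)
  eccentricity <- as.matrix(eccentricity)
  if (!all(dim(r2) == dim(epi_intensity)) ||
      !all(dim(r2) == dim(eccentricity)))
    stop("r2, epi_intensity and eccentricity must have matching dimensions")
  if (is.character(band)) {
    band_lim <- switch(match.arg(band, c("centre", "edge")),
                       centre = c(1, 3), edge = c(3.5, 4.0))
    band_lab <- band
  } else {
    stopifnot(length(band) == 2, band[1] < band[2])
    band_lim <- band; band_lab <- "custom"
  }
  med_r2 <- apply(r2, 1, stats::median)
  min_epi <- apply(epi_intensity, 1, min)
  med_ecc <- apply(eccentricity, 1, stats::median)
  inc <- med_r2 > r2_threshold &
    min_epi >= intensity_threshold &
    med_ecc >= band_lim[1] & med_ecc <= band_lim[2]
  if (!is.null(area) && !is.null(areas)) inc <- inc & area %in% areas
  structure(list(included = inc, band = band_lab,
                 criteria = list(r2_threshold = r2_threshold,
                                 intensity_threshold = intensity_threshold,
                                 eccentricity_band = band_lim)),
            class = "roi_selection")
}
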