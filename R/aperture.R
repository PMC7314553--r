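#' Visual-field aperture movies
#'
#' An `aperture_movie` is a binary (0/1, optionally fractional) occupancy
#' movie on a square visual-field pixel grid: frames x height x width, with
#' degrees-of-visual-angle scaling and the fixation point at the grid centre.
#' Coordinates follow the standard visual-field convention: x increases
#' rightward, y upward, origin at fixation, angles counter-clockwise from the
#' positive x-axis.
#'
#' @param frames numeric array, frames x height x width, values in [0, 1]
#' @param deg_per_pixel degrees of visual angle per pixel (square pixels)
#' @param frame_rate frames per second
#' @return an object of class `aperture_movie`
#' @export
aperture_movie <- function(frames, deg_per_pixel, frame_rate) {
  stopifnot(length(dim(frames)) == 3L, deg_per_pixel > 0, frame_rate > 0)
  if (dim(frames)[2] != dim(frames)[3])
    stop("aperture grid must be square")
  if (any(frames < 0 | frames > 1))
    stop("aperture occupancy values must lie in [0, 1]")
  structure(
    list(frames = frames,
         deg_per_pixel = deg_per_pixel,
         frame_rate = frame_rate,
         centre = (dim(frames)[2] + 1) / 2),
    class = "aperture_movie")
}

#' @export
print.aperture_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "aperture_movie: %d frame(s), %dx%d px (%.3f deg/px, %.4g deg extent), %g fps\n",
    d[1], d[2], d[3], x$deg_per_pixel, d[2] * x$deg_per_pixel, x$frame_rate))
  invisible(x)
}

# Pixel-centre coordinate vectors (deg) for an n x n grid centred on fixation.
pixel_coords <- function(n_px, deg_per_pixel) {
  (seq_len(n_px) - (n_px + 1) / 2) * deg_per_pixel
}

# Wrap angle difference into (-180, 180].
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# Rasterise one sector-cut disk frame: disk of `diameter_deg` minus a sector
# of `mouth_arc_deg` centred at `mouth_angle_deg`. A pixel is occupied iff its
# centre lies inside the shape (no anti-aliasing).
raster_pacman_frame <- function(n_px, deg_per_pixel, diameter_deg,
                                mouth_arc_deg, mouth_angle_deg) {
  xy <- pixel_coords(n_px, deg_per_pixel)
  x <- matrix(xy, n_px, n_px, byrow = TRUE)   # columns = x
  y <- matrix(rev(xy), n_px, n_px)            # rows top-to-bottom = +y down
  r2 <- x^2 + y^2
  inside <- r2 <= (diameter_deg / 2)^2
  if (mouth_arc_deg > 0) {
    theta <- atan2(y, x) * 180 / pi
    in_mouth <- abs(angle_diff(theta, mouth_angle_deg)) <= mouth_arc_deg / 2
    inside <- inside & !in_mouth
  }
  inside * 1
}

#' Render the rotating sector-cut disk ("Pac-Man") aperture movie
#'
#' A luminance disk with a removed sector whose angular position oscillates
#' sinusoidally about the right horizontal meridian,
#' theta(t) = A sin(2 pi f t). With `static = TRUE` the sector is frozen at
#' 0 degrees (the static control condition).
#'
#' @param diameter_deg stimulus diameter, degrees of visual angle (default 7.5)
#' @param mouth_arc_deg arc of the removed sector, degrees (default 70)
#' @param rot_amplitude_deg sinusoidal rotation amplitude A, degrees (default 35)
#' @param rot_freq_hz oscillation rate f, cycles/s (default 0.85)
#' @param duration_s movie duration, seconds
#' @param grid_deg full grid extent, degrees (must cover the stimulus)
#' @param deg_per_pixel grid resolution (default 0.05)
#' @param frame_rate frames/s (default 30)
#' @param static freeze the sector at 0 degrees
#' @return an [aperture_movie]
#' @export
render_pacman_movie <- function(diameter_deg = 7.5, mouth_arc_deg = 70,
                                rot_amplitude_deg = 35, rot_freq_hz = 0.85,
                                duration_s = 1 / 0.85, grid_deg = 8.5,
                                deg_per_pixel = 0.05, frame_rate = 30,
                                static = FALSE) {
  stopifnot(diameter_deg > 0, mouth_arc_deg >= 0, mouth_arc_deg < 360)
  if (frame_rate <= 0) stop("frame rate must be positive")
  if (grid_deg < diameter_deg)
    stop("grid extent smaller than stimulus extent")
  n_px <- round(grid_deg / deg_per_pixel)
  n_frames <- max(1L, round(duration_s * frame_rate))
  t <- (seq_len(n_frames) - 1) / frame_rate
  ang <- if (static) rep(0, n_frames) else
    rot_amplitude_deg * sin(2 * pi * rot_freq_hz * t)
  frames <- array(0, c(n_frames, n_px, n_px))
  for (i in seq_len(n_frames))
    frames[i, , ] <- raster_pacman_frame(n_px, deg_per_pixel, diameter_deg,
                                         mouth_arc_deg, ang[i])
  out <- aperture_movie(frames, deg_per_pixel, frame_rate)
  out$mouth_angle_deg <- ang
  out
}

#' Render the dynamic control aperture movie
#'
#' A stationary left-hand wedge plus a right-hand wedge whose centre angle
#' follows the same sinusoid as the rotating sector of the disk stimulus. The
#' retinal image in the left half-field is constant across frames and matches
#' the disk stimuli.
#'
#' @param stationary_arc_deg arc of the stationary left wedge (default 220)
#' @param rotating_arc_deg arc of the rotating right wedge (default 65)
#' @inheritParams render_pacman_movie
#' @return an [aperture_movie]
#' @export
render_dynamic_control_movie <- function(stationary_arc_deg = 220,
                                         rotating_arc_deg = 65,
                                         rot_amplitude_deg = 35,
                                         rot_freq_hz = 0.85,
                                         duration_s = 1 / 0.85,
                                         diameter_deg = 7.5, grid_deg = 8.5,
                                         deg_per_pixel = 0.05,
                                         frame_rate = 30) {
  stopifnot(stationary_arc_deg > 0, rotating_arc_deg > 0,
            stationary_arc_deg + rotating_arc_deg < 360)
  if (grid_deg < diameter_deg) stop("grid extent smaller than stimulus extent")
  # wedges may not overlap at the rotation extremes: gap between the left
  # wedge edge (180 - arc/2 boundary) and the rotating wedge edge
  max_rot_edge <- rot_amplitude_deg + rotating_arc_deg / 2
  left_edge <- 180 - stationary_arc_deg / 2
  if (max_rot_edge > left_edge)
    stop("rotating and stationary wedges overlap at rotation extremes")
  n_px <- round(grid_deg / deg_per_pixel)
  n_frames <- max(1L, round(duration_s * frame_rate))
  t <- (seq_len(n_frames) - 1) / frame_rate
  ang <- rot_amplitude_deg * sin(2 * pi * rot_freq_hz * t)
  xy <- pixel_coords(n_px, deg_per_pixel)
  x <- matrix(xy, n_px, n_px, byrow = TRUE)
  y <- matrix(rev(xy), n_px, n_px)
  in_disk <- x^2 + y^2 <= (diameter_deg / 2)^2
  theta <- atan2(y, x) * 180 / pi
  left_wedge <- in_disk & abs(angle_diff(theta, 180)) <= stationary_arc_deg / 2
  frames <- array(0, c(n_frames, n_px, n_px))
  for (i in seq_len(n_frames)) {
    right_wedge <- in_disk &
      abs(angle_diff(theta, ang[i])) <= rotating_arc_deg / 2
    frames[i, , ] <- (left_wedge | right_wedge) * 1
  }
  out <- aperture_movie(frames, deg_per_pixel, frame_rate)
  out$wedge_angle_deg <- ang
  out
}

#' Render bar apertures for population receptive field mapping
#'
#' One frame per unique bar configuration: `n_orientations` bar orientations
#' times `n_positions` positions per orientation, bars spanning the mapped
#' field. Returns the movie plus a configuration index table.
#'
#' @param bar_width_deg bar width, degrees (default 1.25)
#' @param n_orientations number of bar orientations (default 4)
#' @param n_positions number of bar positions per orientation (default 8)
#' @param field_deg extent of the mapped field, degrees (default 8.5)
#' @param deg_per_pixel grid resolution
#' @return an [aperture_movie] with a `configs` data.frame
#'   (config, orientation_deg, position_deg) attached
#' @export
render_bar_apertures <- function(bar_width_deg = 1.25, n_orientations = 4,
                                 n_positions = 8, field_deg = 8.5,
                                 deg_per_pixel = 0.05) {
  stopifnot(n_orientations >= 1, n_positions >= 1)
  if (bar_width_deg > field_deg) stop("bar width exceeds field extent")
  n_px <- round(field_deg / deg_per_pixel)
  xy <- pixel_coords(n_px, deg_per_pixel)
  x <- matrix(xy, n_px, n_px, byrow = TRUE)
  y <- matrix(rev(xy), n_px, n_px)
  orientations <- seq(0, 180, length.out = n_orientations + 1)[seq_len(n_orientations)]
  # bar centres span the field symmetrically
  span <- field_deg - bar_width_deg
  positions <- if (n_positions == 1) 0 else
    seq(-span / 2, span / 2, length.out = n_positions)
  n_cfg <- n_orientations * n_positions
  frames <- array(0, c(n_cfg, n_px, n_px))
  cfg <- data.frame(config = seq_len(n_cfg),
                    orientation_deg = rep(orientations, each = n_positions),
                    position_deg = rep(positions, times = n_orientations))
  for (i in seq_len(n_cfg)) {
    th <- cfg$orientation_deg[i] * pi / 180
    # signed distance from the bar axis (bar oriented along `th`)
    d <- -x * sin(th) + y * cos(th)
    frames[i, , ] <- (abs(d - cfg$position_deg[i]) <= bar_width_deg / 2) * 1
  }
  out <- aperture_movie(frames, deg_per_pixel, frame_rate = 1)
  out$configs <- cfg
  out
}
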