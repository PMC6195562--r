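#' Beamforming pixel grid
#'
#' Pixel grid of the beamformed image in the probe frame. The origin
#' convention is the center of the top row: lateral coordinate 0 is the
#' array center (column `(n_lateral - 1) / 2`, 0-based), and the top row
#' sits at depth `z_min`. Defaults follow conventional line-per-element
#' delay-and-sum: one lateral line per element (spacing = pitch) and
#' axial spacing of one sample (`c / fs`).
#'
#' @param geom a [transducer_geometry()]
#' @param sound_speed m/s (used for the default axial spacing)
#' @param z_min,z_max depth range, mm
#' @param lateral_spacing mm (default: element pitch)
#' @param n_lateral number of image lines (default: `n_elements`)
#' @param axial_spacing mm (default: `c / fs`)
#' @return an object of class `image_grid`
#' @export
image_grid <- function(geom, sound_speed = 1540, z_min = 2, z_max = 38,
                       lateral_spacing = geom$pitch,
                       n_lateral = geom$n_elements,
                       axial_spacing = sound_speed / 1000 /
                         geom$sampling_frequency) {
  stopifnot(lateral_spacing > 0, axial_spacing > 0, z_max > z_min, z_min > 0)
  if ((n_lateral - 1) * lateral_spacing >
      (geom$n_elements - 1) * geom$pitch + 1e-9)
    stop("lateral extent exceeds the array aperture")
  n_axial <- floor((z_max - z_min) / axial_spacing) + 1L
  structure(list(n_axial = as.integer(n_axial),
                 n_lateral = as.integer(n_lateral),
                 axial_spacing = axial_spacing,
                 lateral_spacing = lateral_spacing,
                 z_min = z_min),
            class = "image_grid")
}

#' Lateral pixel coordinates (mm, 0 at the array center)
#' @param grid an [image_grid()]
#' @export
grid_lateral <- function(grid) {
  (seq_len(grid$n_lateral) - 1 - (grid$n_lateral - 1) / 2) *
    grid$lateral_spacing
}

#' Axial pixel coordinates (depth, mm)
#' @param grid an [image_grid()]
#' @export
grid_axial <- function(grid) {
  grid$z_min + (seq_len(grid$n_axial) - 1) * grid$axial_spacing
}

#' Convert a (row, col) pixel to image-frame mm
#'
#' Image-frame coordinates are measured from the center of the top row:
#' lateral offset from the array center and depth below the transducer
#' face. `row`/`col` are 1-based and may be fractional (centroids).
#'
#' @param grid an [image_grid()]
#' @param row,col pixel coordinates (1-based, fractional allowed)
#' @return c(lateral, axial) in mm
#' @export
pixel_to_mm <- function(grid, row, col) {
  c(lateral = (col - 1 - (grid$n_lateral - 1) / 2) * grid$lateral_spacing,
    axial = grid$z_min + (row - 1) * grid$axial_spacing)
}

#' Default display window for the experiment harnesses
#'
#' A 5-35 mm depth window with axial sampling at half the RF rate
#' (2 c / fs). Tip localization is centroid-based and insensitive to
#' axial sampling at this scale, so the closed-loop harnesses use this
#' lighter grid; resolution measurements keep the full-rate grid of
#' [image_grid()].
#'
#' @param geom a [transducer_geometry()]
#' @param sound_speed m/s
#' @return an [image_grid()]
#' @export
experiment_grid <- function(geom, sound_speed = 1540) {
  image_grid(geom, sound_speed, z_min = 5, z_max = 35,
             axial_spacing = 2 * sound_speed / 1000 /
               geom$sampling_frequency)
}

#' Delay-and-sum beamforming (receive-only)
#'
#' Photoacoustic delay-and-sum: each pixel sums the channel samples of
#' every receive element inside a depth-proportional aperture, delayed by
#' the one-way time of flight from the pixel to the element, with linear
#' interpolation between samples. The aperture grows with depth at a
#' fixed F-number and is Hann-apodized by default; the sum is normalized
#' by the apodization weights. `f_number = 0` uses the full aperture with
#' uniform weights (useful for oracle comparisons).
#'
#' @param frame a `channel_frame`
#' @param geom a [transducer_geometry()]
#' @param grid an [image_grid()]
#' @param sound_speed m/s
#' @param f_number receive F-number (depth / aperture width); default 3.3,
#'   calibrated so a thread target images near 2 mm lateral FWHM
#' @param apodization "hann" or "uniform"
#' @return n_axial x n_lateral matrix of beamformed RF values
#' @export
das_beamform <- function(frame, geom, grid, sound_speed = 1540,
                         f_number = 3.3, apodization = c("hann", "uniform")) {
  if (sound_speed <= 0) stop("sound_speed must be positive")
  apodization <- match.arg(apodization)
  stopifnot(inherits(frame, "channel_frame"),
            ncol(frame$samples) == geom$n_elements)
  das_core(frame$samples, element_positions(geom),
           grid_lateral(grid), grid_axial(grid),
           sound_speed / 1000, frame$sampling_frequency,
           f_number, if (apodization == "hann") 1L else 0L)
}

#' Envelope detection
#'
#' Magnitude of the analytic signal along the axial (first) dimension,
#' computed with the FFT: positive frequencies doubled, negative zeroed.
#' For a pure axial sinusoid of amplitude A the interior of the output is
#' approximately A.
#'
#' @param rf_image numeric matrix (axial x lateral) of beamformed RF
#' @return nonnegative matrix of the same size
#' @export
envelope_detect <- function(rf_image) {
  rf_image <- as.matrix(rf_image)
  if (!all(is.finite(rf_image))) stop("rf_image must be finite")
  n <- nrow(rf_image)
  if (n < 2) return(abs(rf_image))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  analytic <- mvfft(mvfft(rf_image) * h, inverse = TRUE) / n
  Mod(analytic)
}

#' Construct a photoacoustic image object
#'
#' @param envelope nonnegative matrix (axial x lateral)
#' @param grid the [image_grid()] the envelope was beamformed on
#' @return an object of class `pa_image`
#' @export
pa_image <- function(envelope, grid) {
  envelope <- as.matrix(envelope)
  stopifnot(all(is.finite(envelope)), all(envelope >= 0),
            nrow(envelope) == grid$n_axial, ncol(envelope) == grid$n_lateral)
  structure(list(envelope = envelope, grid = grid), class = "pa_image")
}

#' @export
print.pa_image <- function(x, ...) {
  cat(sprintf("<pa_image> %d x %d px (%.3g x %.3g mm/px), peak %.3g\n",
              x$grid$n_axial, x$grid$n_lateral, x$grid$axial_spacing,
              x$grid$lateral_spacing, max(x$envelope)))
  invisible(x)
}

#' Simulate, beamform and envelope-detect one frame
#'
#' Convenience wrapper running the acquisition chain for one laser shot.
#'
#' @inheritParams simulate_channel_frame
#' @inheritParams das_beamform
#' @param grid an [image_grid()]
#' @return a [pa_image()]
#' @export
acquire_image <- function(source, geom, medium, grid, pose = probe_pose(),
                          seed = NULL, n_samples = 1024L, f_number = 3.3,
                          frame_index = 0L) {
  frame <- simulate_channel_frame(source, geom, medium, pose, seed,
                                  n_samples, frame_index)
  rf <- das_beamform(frame, geom, grid, medium$sound_speed, f_number)
  pa_image(envelope_detect(rf), grid)
}

#' Log compression for display
#'
#' `20 * log10(envelope / max(envelope))`, clipped at `-dynamic_range`;
#' the brightest pixel maps to 0 dB.
#'
#' @param envelope nonnegative matrix or a `pa_image`
#' @param dynamic_range dB (> 0), e.g. 30 for channel-quality displays,
#'   60 for tissue overlays
#' @return matrix of dB values in `[-dynamic_range, 0]`
#' @export
log_compress <- function(envelope, dynamic_range = 30) {
  if (inherits(envelope, "pa_image")) envelope <- envelope$envelope
  if (dynamic_range <= 0) stop("dynamic_range must be positive")
  m <- max(envelope)
  if (m <= 0) stop("cannot log-compress an all-zero envelope")
  db <- envelope
  db[] <- -Inf
  pos <- envelope > 0
  db[pos] <- 20 * log10(envelope[pos] / m)
  pmax(db, -dynamic_range)
}
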