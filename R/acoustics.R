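#' Linear-array transducer geometry
#'
#' Describes the receive array: element count and pitch set the lateral
#' aperture, center frequency and -6 dB fractional bandwidth set the
#' band-limited pulse model, and the elevation beamwidth sets the Gaussian
#' out-of-plane sensitivity profile. Defaults describe a 5.5 MHz, 61%
#' fractional bandwidth linear array with 128 elements at 0.3 mm pitch
#' (38.4 mm field of view) sampled at 40 MHz.
#'
#' `psf_axial_scale` is a system impulse-response calibration factor: the
#' transducer's nominal -6 dB bandwidth describes the element alone, while
#' the axial extent of the measured point-spread function of the full
#' system (laser pulse, acoustic source size, receive electronics) is
#' broader. The default is calibrated once so that a simulated 0.35 mm
#' thread target images with about 1 mm axial and, together with the
#' beamformer's F-number, about 2 mm lateral full width at half maximum
#' over 1-3 cm depths.
#'
#' @param n_elements number of array elements (>= 2)
#' @param pitch element pitch, mm
#' @param center_frequency MHz
#' @param fractional_bandwidth -6 dB fractional bandwidth, in (0, 2)
#' @param sampling_frequency MHz, must exceed twice the center frequency
#' @param elevation_beamwidth full width at half maximum of the Gaussian
#'   elevation sensitivity profile, mm
#' @param psf_axial_scale multiplier on the pulse envelope duration
#'   (system impulse-response calibration; see Details)
#' @return an object of class `transducer_geometry`
#' @export
transducer_geometry <- function(n_elements = 128L, pitch = 0.3,
                                center_frequency = 5.5,
                                fractional_bandwidth = 0.61,
                                sampling_frequency = 40,
                                elevation_beamwidth = 3,
                                psf_axial_scale = 3.5) {
  stopifnot(n_elements >= 2, pitch > 0,
            fractional_bandwidth > 0, fractional_bandwidth < 2,
            center_frequency > 0,
            sampling_frequency > 2 * center_frequency,
            elevation_beamwidth > 0, psf_axial_scale > 0)
  structure(list(n_elements = as.integer(n_elements), pitch = pitch,
                 center_frequency = center_frequency,
                 fractional_bandwidth = fractional_bandwidth,
                 sampling_frequency = sampling_frequency,
                 elevation_beamwidth = elevation_beamwidth,
                 psf_axial_scale = psf_axial_scale),
            class = "transducer_geometry")
}

#' @export
print.transducer_geometry <- function(x, ...) {
  cat(sprintf(paste0("<transducer_geometry> %d elements x %.2f mm pitch ",
                     "(aperture %.1f mm), f0 %.1f MHz, BW %.0f%%, fs %.0f MHz\n"),
              x$n_elements, x$pitch, (x$n_elements - 1) * x$pitch,
              x$center_frequency, 100 * x$fractional_bandwidth,
              x$sampling_frequency))
  invisible(x)
}

#' Lateral element positions, centered on zero
#'
#' @param geom a [transducer_geometry()]
#' @return numeric vector of length `n_elements`, mm
#' @export
element_positions <- function(geom) {
  (seq_len(geom$n_elements) - 1 - (geom$n_elements - 1) / 2) * geom$pitch
}

# ---------------------------------------------------------------------------
# Tissue presets

.preset_table <- function() {
  # sound_speed m/s; attenuation dB/cm/MHz; noise_sigma in channel units
  # (the fiber source at default energy peaks near 175 channel units at
  # 20 mm depth in water); deflection_sigma mm per advancement step.
  # noise_sigma / deflection_sigma / clutter_level are calibration knobs:
  # the physical media were not quantified, so values are chosen to give
  # realistic channel SNR and the observed tissue ordering of tracking
  # error (smallest in water and muscle, largest through skull).
  list(
    water = list(sound_speed = 1480, amplitude_scale = 1.00,
                 noise_sigma = 0.5, clutter_level = 0,
                 attenuation = 0.002, deflection_sigma = 0),
    chicken_thigh = list(sound_speed = 1540, amplitude_scale = 0.85,
                         noise_sigma = 5, clutter_level = 0,
                         attenuation = 0.7, deflection_sigma = 0.45),
    chicken_thigh_clutter = list(sound_speed = 1540, amplitude_scale = 0.85,
                                 noise_sigma = 5, clutter_level = 0.5,
                                 attenuation = 0.7, deflection_sigma = 0.5),
    fat = list(sound_speed = 1450, amplitude_scale = 0.80,
               noise_sigma = 6, clutter_level = 0,
               attenuation = 0.6, deflection_sigma = 0.6),
    muscle = list(sound_speed = 1580, amplitude_scale = 0.90,
                  noise_sigma = 4, clutter_level = 0,
                  attenuation = 0.8, deflection_sigma = 0.2),
    liver = list(sound_speed = 1570, amplitude_scale = 0.85,
                 noise_sigma = 6, clutter_level = 0,
                 attenuation = 0.5, deflection_sigma = 0.7),
    brain_skull = list(sound_speed = 1540, amplitude_scale = 0.80,
                       noise_sigma = 7, clutter_level = 0,
                       attenuation = 1.2, deflection_sigma = 0.9)
  )
}

#' Names of the built-in tissue presets
#' @return character vector
#' @export
tissue_preset_names <- function() names(.preset_table())

#' Tissue medium preset
#'
#' Returns the acoustic parameters of one of the built-in media: water
#' (control: no scattering, no deflection, smallest noise floor), chicken
#' thigh with and without a clutter-generating wire-mesh layer, fat
#' (chicken breast), muscle (sirloin), liver, and brain imaged through a
#' thinned skull (largest attenuation). `clutter_level` scales a
#' band-limited, element-correlated noise term relative to the source
#' peak; `deflection_sigma` is the per-step random deviation of the
#' needle tip from its commanded path used by the experiment harnesses.
#'
#' @param name one of [tissue_preset_names()]
#' @return an object of class `medium_preset`
#' @export
tissue_preset <- function(name) {
  tab <- .preset_table()
  if (!is.character(name) || length(name) != 1 || !name %in% names(tab)) {
    stop("unknown tissue preset ", deparse(substitute(name)), ": '", name,
         "'. Valid names: ", paste(names(tab), collapse = ", "))
  }
  structure(c(list(name = name), tab[[name]]), class = "medium_preset")
}

#' @export
print.medium_preset <- function(x, ...) {
  cat(sprintf(paste0("<medium_preset> %s: c=%.0f m/s, atten=%.3g dB/cm/MHz, ",
                     "noise=%.2g, clutter=%.2g, deflection=%.2g mm\n"),
              x$name, x$sound_speed, x$attenuation, x$noise_sigma,
              x$clutter_level, x$deflection_sigma))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Fiber source and fluence

#' Fiber-tip photoacoustic source
#'
#' A point-like optical absorber at the tip of an optical fiber threaded
#' through the needle. Position is (x lateral, y elevation, z depth) in
#' the world frame, mm. Default energy of 2.75 mJ through a 1 mm core
#' gives approximately 350 mJ/cm^2 fluence at the fiber tip.
#'
#' @param position numeric length-3, mm
#' @param pulse_energy mJ (>= 0)
#' @param core_diameter fiber core diameter, mm (> 0)
#' @return an object of class `fiber_source`
#' @export
fiber_source <- function(position = c(0, 0, 20), pulse_energy = 2.75,
                         core_diameter = 1) {
  stopifnot(length(position) == 3, is.finite(position),
            pulse_energy >= 0, core_diameter > 0, position[3] > 0)
  structure(list(position = as.numeric(position),
                 pulse_energy = pulse_energy,
                 core_diameter = core_diameter),
            class = "fiber_source")
}

#' Convert pulse energy to fluence at the fiber tip
#'
#' Fluence is energy divided by the fiber core cross-sectional area:
#' `E / (pi * (d/2)^2)` with the diameter converted to cm. 1.58 mJ through
#' a 1 mm core gives 201.2 mJ/cm^2.
#'
#' @param pulse_energy mJ
#' @param core_diameter mm
#' @return fluence, mJ/cm^2
#' @export
energy_to_fluence <- function(pulse_energy, core_diameter) {
  if (any(core_diameter <= 0)) stop("core_diameter must be positive")
  if (any(pulse_energy < 0)) stop("pulse_energy must be >= 0")
  pulse_energy / (pi * (core_diameter / 20)^2)
}

#' Inverse of [energy_to_fluence()]
#' @param fluence mJ/cm^2
#' @param core_diameter mm
#' @return pulse energy, mJ
#' @export
fluence_to_energy <- function(fluence, core_diameter) {
  if (any(core_diameter <= 0)) stop("core_diameter must be positive")
  fluence * pi * (core_diameter / 20)^2
}

#' Gaussian elevation sensitivity
#'
#' Out-of-plane sensitivity of the array: 1 in the imaging plane, 0.5 at
#' half the beamwidth (FWHM convention), and strictly decreasing in
#' |offset|. Targets a few beamwidths out of plane are effectively
#' invisible, which is what triggers the servo's search behavior.
#'
#' @param y_offset elevation offset from the imaging plane, mm
#' @param beamwidth FWHM of the profile, mm
#' @return weight in \[0, 1\]
#' @export
elevation_weight <- function(y_offset, beamwidth) {
  if (any(beamwidth <= 0)) stop("beamwidth must be positive")
  exp(-4 * log(2) * (y_offset / beamwidth)^2)
}

# ---------------------------------------------------------------------------
# Channel-data simulation

#' Probe pose as a rigid transform
#'
#' Builds the 4x4 probe-to-world transform for a probe at `position`
#' (mm) with its axes aligned to the world frame (x lateral, y elevation,
#' z depth, pointing into the tissue). A rotation can be supplied for
#' tilted probes.
#'
#' @param position numeric length-3, mm
#' @param rotation 3x3 rotation matrix (default identity)
#' @return 4x4 rigid transform matrix
#' @export
probe_pose <- function(position = c(0, 0, 0), rotation = diag(3)) {
  stopifnot(length(position) == 3, all(dim(rotation) == c(3, 3)))
  T <- diag(4)
  T[1:3, 1:3] <- rotation
  T[1:3, 4] <- position
  T
}

.check_rigid <- function(T, what = "transform") {
  if (!is.matrix(T) || !all(dim(T) == c(4, 4)) || !all(is.finite(T)))
    stop(what, " must be a finite 4x4 matrix")
  R <- T[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8)
    stop(what, " is not a rigid transform (rotation not orthonormal)")
  if (any(abs(T[4, ] - c(0, 0, 0, 1)) > 1e-12))
    stop(what, " last row must be (0, 0, 0, 1)")
  invisible(TRUE)
}

.pulse_sigma_us <- function(geom) {
  # -6 dB (amplitude half-maximum) full spectral width = fbw * f0 for a
  # Gaussian spectrum => sigma_f = fbw * f0 / (2 sqrt(2 ln 2)); the time
  # envelope is Gaussian with sigma_t = 1 / (2 pi sigma_f), broadened by
  # the system impulse-response calibration factor.
  sigma_f <- geom$fractional_bandwidth * geom$center_frequency /
    (2 * sqrt(2 * log(2)))
  geom$psf_axial_scale / (2 * pi * sigma_f)
}

#' Sample times of a channel frame
#' @param frame a `channel_frame`
#' @return time of each sample, us (first sample is t = 0)
#' @export
channel_time <- function(frame) {
  (seq_len(nrow(frame$samples)) - 1) / frame$sampling_frequency
}

# band-limited (Gaussian band around f0), element-correlated noise field
# used as the acoustic-clutter surrogate; unit RMS before scaling
.clutter_field <- function(n_samples, n_elements, geom, corr_elements = 4) {
  w <- matrix(rnorm(n_samples * n_elements), n_samples, n_elements)
  f <- (seq_len(n_samples) - 1) / n_samples * geom$sampling_frequency
  f <- pmin(f, geom$sampling_frequency - f)         # two-sided
  sigma_f <- geom$fractional_bandwidth * geom$center_frequency /
    (2 * sqrt(2 * log(2)))
  H <- exp(-(f - geom$center_frequency)^2 / (2 * sigma_f^2))
  band <- Re(mvfft(mvfft(w) * H, inverse = TRUE)) / n_samples
  # correlate across neighboring elements with a Gaussian kernel
  idx <- seq_len(n_elements)
  K <- exp(-0.5 * outer(idx, idx, "-")^2 / corr_elements^2)
  K <- K / rowSums(K)
  sm <- band %*% t(K)
  sm / sqrt(mean(sm^2))
}

#' Simulate one photoacoustic channel-data frame
#'
#' Produces the raw per-element time series recorded after one laser
#' shot: a band-limited (Gaussian-modulated sinusoid) pulse arrives at
#' each element after the one-way time of flight from the fiber tip, with
#' 1/r spherical spreading, a frequency-independent attenuation factor
#' `10^(-attenuation * f0 * depth_cm / 20)` applied at the source depth,
#' and the Gaussian elevation sensitivity of the array. Additive white
#' electronic noise (`noise_sigma`) and, when `clutter_level > 0`, a
#' band-limited element-correlated clutter term scaled to
#' `clutter_level` times the peak of the clean signal model the
#' degradations seen through heterogeneous near-field layers.
#'
#' Signal amplitude is proportional to
#' `energy_to_fluence(source) * amplitude_scale`, normalized so the
#' default source peaks near `fluence / 2` channel units at 20 mm depth.
#'
#' @param source a [fiber_source()] (world frame)
#' @param geom a [transducer_geometry()]
#' @param medium a [tissue_preset()] or compatible list
#' @param pose 4x4 probe-to-world rigid transform (see [probe_pose()])
#' @param seed integer seed; the frame is a deterministic function of its
#'   arguments. `NULL` draws from the current RNG stream.
#' @param n_samples samples per element (default 1024)
#' @param frame_index bookkeeping index stored on the frame
#' @return an object of class `channel_frame` with fields `samples`
#'   (n_samples x n_elements matrix), `sampling_frequency`, `frame_index`
#' @export
simulate_channel_frame <- function(source, geom, medium,
                                   pose = probe_pose(), seed = NULL,
                                   n_samples = 1024L, frame_index = 0L) {
  .check_rigid(pose, "pose")
  run <- function() {
    sp <- solve(pose) %*% c(source$position, 1)   # source in probe frame
    sx <- sp[1]; sy <- sp[2]; sz <- sp[3]
    if (sz <= 0) stop("source is behind the array (z <= 0 in probe frame)")
    ex <- element_positions(geom)
    r <- sqrt((ex - sx)^2 + sy^2 + sz^2)          # mm, per element
    c_mm_us <- medium$sound_speed / 1000
    tau <- r / c_mm_us                            # us
    t_max <- (n_samples - 1) / geom$sampling_frequency
    if (sz / c_mm_us > t_max)
      stop("source depth outside the sampled time window")
    fluence <- energy_to_fluence(source$pulse_energy, source$core_diameter)
    atten <- 10^(-medium$attenuation * geom$center_frequency * (r / 10) / 20)
    amp <- fluence * medium$amplitude_scale * (10 / r) * atten *
      elevation_weight(sy, geom$elevation_beamwidth)
    sigma_t <- .pulse_sigma_us(geom)
    tt <- (seq_len(n_samples) - 1) / geom$sampling_frequency
    dt <- outer(tt, tau, "-")
    sig <- cos(2 * pi * geom$center_frequency * dt) *
      exp(-dt^2 / (2 * sigma_t^2))
    sig <- sweep(sig, 2, amp, "*")
    out <- sig
    if (medium$clutter_level > 0 && max(abs(sig)) > 0) {
      cl <- .clutter_field(n_samples, geom$n_elements, geom)
      cl <- cl / max(abs(cl)) * medium$clutter_level * max(abs(sig))
      out <- out + cl
    }
    if (medium$noise_sigma > 0)
      out <- out + matrix(rnorm(length(out), sd = medium$noise_sigma),
                          n_samples, geom$n_elements)
    structure(list(samples = out,
                   sampling_frequency = geom$sampling_frequency,
                   frame_index = as.integer(frame_index)),
              class = "channel_frame")
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' @export
print.channel_frame <- function(x, ...) {
  cat(sprintf("<channel_frame> %d samples x %d elements @ %.0f MHz (frame %d)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_frequency,
              x$frame_index))
  invisible(x)
}
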