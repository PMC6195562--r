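# Image- and channel-quality statistics.
#
# Convention fixed across the package: standard deviations are population
# standard deviations (divide by N, not N - 1).

.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

.region_values <- function(image, region) {
  if (inherits(image, "pa_image")) image <- image$envelope
  if (is.matrix(region) || is.data.frame(region)) {
    region <- as.matrix(region)
    stopifnot(ncol(region) == 2)
    image[region]
  } else if (is.logical(region)) {
    image[region]
  } else {
    stop("region must be a logical mask or a two-column (row, col) matrix")
  }
}

#' Image contrast between a target and a background region
#'
#' `Contrast = 20 * log10(S_i / S_o)` where `S_i` and `S_o` are the mean
#' envelope values inside and outside the needle-tip signal, taken at the
#' same depth. Invariant under global image scaling.
#'
#' @param image a `pa_image` or envelope matrix
#' @param inside,outside logical masks or two-column (row, col) index
#'   matrices; must be non-empty and disjoint
#' @return contrast, dB
#' @export
contrast <- function(image, inside, outside) {
  si <- .region_values(image, inside)
  so <- .region_values(image, outside)
  if (!length(si) || !length(so)) stop("regions must be non-empty")
  if (mean(so) <= 0) stop("contrast undefined: outside mean is zero")
  20 * log10(mean(si) / mean(so))
}

#' Image signal-to-noise ratio
#'
#' `SNR = S_i / sigma_o`: mean envelope inside the target region divided
#' by the population standard deviation of the background region.
#'
#' @inheritParams contrast
#' @return SNR (dimensionless ratio)
#' @export
snr_image <- function(image, inside, outside) {
  si <- .region_values(image, inside)
  so <- .region_values(image, outside)
  if (!length(si) || length(so) < 2) stop("regions too small")
  s <- .pop_sd(so)
  if (s <= 0) stop("SNR undefined: outside region has zero variance")
  mean(si) / s
}

#' Channel signal-to-noise ratio
#'
#' RMS of the raw channel data in a signal gate divided by the RMS in a
#' noise gate, both taken before beamforming. Gates are given as
#' `list(samples = , elements = )` index vectors.
#'
#' @param frame a `channel_frame`
#' @param signal_gate,noise_gate lists with `samples` and `elements`
#'   index vectors; non-empty, disjoint windows
#' @return ratio of RMS amplitudes
#' @export
channel_snr <- function(frame, signal_gate, noise_gate) {
  g <- function(gate) {
    v <- frame$samples[gate$samples, gate$elements, drop = FALSE]
    if (!length(v)) stop("empty gate")
    sqrt(mean(v^2))
  }
  rs <- g(signal_gate)
  rn <- g(noise_gate)
  if (rn <= 0) stop("channel SNR undefined: noise gate RMS is zero")
  rs / rn
}

#' Default channel-SNR gates for a known source
#'
#' Signal gate: +/- 1 us around the analytic arrival time at the central
#' 16 elements. Noise gate: a pre-arrival window of equal size on the
#' same elements, ending 1 us before the earliest arrival.
#'
#' @param source a [fiber_source()] (world frame)
#' @param geom a [transducer_geometry()]
#' @param medium a [tissue_preset()]
#' @param pose probe pose (4x4)
#' @param n_samples samples in the frame the gates will index
#' @return list(signal_gate, noise_gate)
#' @export
default_snr_gates <- function(source, geom, medium, pose = probe_pose(),
                              n_samples = 1024L) {
  sp <- solve(pose) %*% c(source$position, 1)
  ex <- element_positions(geom)
  ne <- geom$n_elements
  central <- order(abs(ex))[seq_len(min(16L, ne))]
  r <- sqrt((ex[central] - sp[1])^2 + sp[2]^2 + sp[3]^2)
  tau <- r / (medium$sound_speed / 1000)               # us
  fs <- geom$sampling_frequency
  half <- round(1 * fs)                                # 1 us in samples
  ctr <- round(mean(tau) * fs) + 1
  sig <- max(1L, ctr - half):min(n_samples, ctr + half)
  n_len <- length(sig)
  n_end <- max(1L, min(sig) - half)
  noise <- max(1L, n_end - n_len + 1L):n_end
  list(signal_gate = list(samples = sig, elements = sort(central)),
       noise_gate = list(samples = noise, elements = sort(central)))
}

#' Full width at half maximum of the dominant peak
#'
#' Takes the profile through the global envelope maximum along the
#' requested axis, finds the half-maximum crossings by linear
#' interpolation between pixels, and returns the width in mm. Errors if
#' the peak touches the image border or a crossing is missing on either
#' side (unmeasurable peak).
#'
#' @param image a `pa_image`
#' @param axis "lateral" or "axial"
#' @return FWHM, mm
#' @export
measure_fwhm <- function(image, axis = c("lateral", "axial")) {
  axis <- match.arg(axis)
  env <- image$envelope
  pk <- which(env == max(env), arr.ind = TRUE)[1, ]
  profile <- if (axis == "lateral") env[pk[1], ] else env[, pk[2]]
  spacing <- if (axis == "lateral") image$grid$lateral_spacing else
    image$grid$axial_spacing
  ip <- which.max(profile)
  if (ip == 1 || ip == length(profile))
    stop("peak lies on the image border: FWHM unmeasurable")
  half <- profile[ip] / 2
  left <- NA_real_
  for (i in ip:2) {
    if (profile[i - 1] < half) {
      left <- (i - 1) + (half - profile[i - 1]) / (profile[i] - profile[i - 1])
      break
    }
  }
  right <- NA_real_
  for (i in ip:(length(profile) - 1)) {
    if (profile[i + 1] < half) {
      right <- i + (profile[i] - half) / (profile[i] - profile[i + 1])
      break
    }
  }
  if (is.na(left) || is.na(right))
    stop("half-maximum crossing not found: FWHM unmeasurable")
  (right - left) * spacing
}

#' Simulated system resolution at a thread target
#'
#' Images a 0.35 mm diameter thread (modeled as a disc of sub-resolution
#' point sources in the lateral-axial plane) at the requested depths with
#' noise-free water-like settings and returns the lateral and axial FWHM
#' at each depth. Used to calibrate and to regression-test the default
#' point-spread function (about 2 mm lateral, 1 mm axial over 1-3 cm).
#'
#' @param depths mm
#' @param geom a [transducer_geometry()]
#' @param f_number receive F-number passed to [das_beamform()]
#' @param thread_diameter mm
#' @return data.frame(depth, lateral_fwhm, axial_fwhm)
#' @export
measure_system_resolution <- function(depths = c(10, 20, 30),
                                      geom = transducer_geometry(),
                                      f_number = 3.3,
                                      thread_diameter = 0.35) {
  medium <- list(name = "calibration", sound_speed = 1540,
                 amplitude_scale = 1, noise_sigma = 0, clutter_level = 0,
                 attenuation = 0, deflection_sigma = 0)
  grid <- image_grid(geom, medium$sound_speed)
  # thread cross-section: ring of sub-sources inside the diameter
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  rr <- thread_diameter / 2
  offs <- rbind(c(0, 0), cbind(rr * cos(th), rr * sin(th)),
                cbind(rr / 2 * cos(th), rr / 2 * sin(th)))
  res <- lapply(depths, function(z0) {
    rf <- 0
    for (i in seq_len(nrow(offs))) {
      src <- fiber_source(c(offs[i, 1], 0, z0 + offs[i, 2]))
      fr <- simulate_channel_frame(src, geom, medium, seed = 1L)
      rf <- rf + das_beamform(fr, geom, grid, medium$sound_speed, f_number)
    }
    img <- pa_image(envelope_detect(rf), grid)
    data.frame(depth = z0,
               lateral_fwhm = measure_fwhm(img, "lateral"),
               axial_fwhm = measure_fwhm(img, "axial"))
  })
  do.call(rbind, res)
}

#' Summary statistics of an error sample
#'
#' Mean, population standard deviation, RMS and count. These satisfy
#' `rms^2 = mean^2 + variance` by construction.
#'
#' @param errors numeric vector, mm
#' @return list(mean, std, rms, n) of class `summary_stats`
#' @export
summarize_errors <- function(errors) {
  errors <- as.numeric(errors)
  if (!length(errors) || any(!is.finite(errors)))
    stop("errors must be a non-empty finite numeric vector")
  structure(list(mean = mean(errors), std = .pop_sd(errors),
                 rms = sqrt(mean(errors^2)), n = length(errors)),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("mean %.3f mm, sd %.3f mm, rms %.3f mm (n = %d)\n",
              x$mean, x$std, x$rms, x$n))
  invisible(x)
}

#' One-way ANOVA across groups of centering errors
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test), as used
#' to compare probe-centering errors across tissue media.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values)
#' @return list(statistic = F, p_value, df)
#' @export
anova_one_way <- function(groups) {
  if (!is.list(groups) || length(groups) < 2 ||
      any(vapply(groups, length, 1L) < 2))
    stop("need at least 2 groups with at least 2 values each")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (.pop_sd(values) == 0)
    return(list(statistic = 0, p_value = 1,
                df = c(length(groups) - 1L, length(values) - length(groups))))
  ft <- oneway.test(values ~ g, var.equal = TRUE)
  list(statistic = unname(ft$statistic), p_value = unname(ft$p.value),
       df = unname(ft$parameter))
}
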