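# Experiment harnesses: needle tracking, probe centering,
# angled-insertion / perturbation recovery, and the fluence sweep.

.resolve_preset <- function(preset) {
  if (inherits(preset, "medium_preset")) preset else tissue_preset(preset)
}

#' Needle tracking experiment
#'
#' The probe is held fixed with its lateral axis parallel to the needle;
#' the needle is advanced `step_mm` per step for `n_steps` steps (13 mm
#' total at the defaults). The true tip position deviates from the
#' commanded path by a per-step Gaussian deflection of scale
#' `deflection_sigma` in the lateral and axial directions (zero in
#' water), modeling needle-tip deflection in tissue. At each position
#' the tip is segmented from a single acquisition; the tracking error per
#' step is the absolute difference between the measured inter-position
#' distance `|p_b - p_a|` and the ground-truth stage reading `step_mm`.
#'
#' @param preset a [tissue_preset()] or preset name
#' @param n_steps advancement steps (default 10)
#' @param step_mm stage translation per step, mm (default 1.3)
#' @param deflection_sigma per-step deflection scale, mm; defaults to the
#'   preset's value
#' @param seed integer seed
#' @param source_depth tip depth, mm
#' @param pulse_energy mJ
#' @param geom,seg_params,n_samples,f_number acquisition settings
#' @return data.frame with one row per step: measured and true distances,
#'   tracking error (mm) and segmentation success
#' @export
run_tracking_experiment <- function(preset, n_steps = 10L, step_mm = 1.3,
                                    deflection_sigma = NULL, seed = 1L,
                                    source_depth = 20, pulse_energy = 2.75,
                                    geom = transducer_geometry(),
                                    seg_params = segmentation_params(),
                                    n_samples = 1024L, f_number = 3.3) {
  medium <- .resolve_preset(preset)
  if (is.null(deflection_sigma)) deflection_sigma <- medium$deflection_sigma
  grid <- experiment_grid(geom, medium$sound_speed)
  fov <- (grid$n_lateral - 1) * grid$lateral_spacing
  if (n_steps * step_mm > fov)
    stop("total translation exceeds the lateral field of view")
  x0 <- -n_steps * step_mm / 2
  withr::with_seed(as.integer(seed), {
    defl <- matrix(rnorm(2 * (n_steps + 1), sd = deflection_sigma),
                   ncol = 2)
    positions <- cbind(x = x0 + (0:n_steps) * step_mm + defl[, 1],
                       z = source_depth + defl[, 2])
  })
  measured <- matrix(NA_real_, n_steps + 1, 2)
  found <- logical(n_steps + 1)
  for (k in 0:n_steps) {
    src <- fiber_source(c(positions[k + 1, 1], 0, positions[k + 1, 2]),
                        pulse_energy = pulse_energy)
    step_seed <- (as.integer(seed) * 10007L + k * 104729L) %% 2147483647L
    img <- acquire_image(src, geom, medium, grid, seed = step_seed,
                         n_samples = n_samples, f_number = f_number,
                         frame_index = k)
    det <- segment_frame(img, seg_params)
    found[k + 1] <- det$found
    if (det$found) measured[k + 1, ] <- det$tip_mm
  }
  d_meas <- sqrt(rowSums((measured[-1, , drop = FALSE] -
                            measured[-(n_steps + 1), , drop = FALSE])^2))
  data.frame(step = seq_len(n_steps),
             measured_mm = d_meas,
             truth_mm = step_mm,
             error_mm = abs(d_meas - step_mm),
             found = found[-1] & found[-(n_steps + 1)],
             tissue = medium$name, seed = as.integer(seed))
}

#' Probe centering experiment
#'
#' For each trial the probe starts with a random lateral offset (up to
#' `initial_offset_range` mm) from a stationary tip, the servo loop runs
#' to quiescence, and the residual lateral distance `d_p` between the
#' segmented signal and the image center is recorded from the final
#' frame. Non-convergence (no detection at the end, or a search timeout)
#' marks the trial failed rather than raising an error.
#'
#' @param preset a [tissue_preset()] or preset name
#' @param n_trials number of trials (default 10)
#' @param initial_offset_range maximum |initial lateral offset|, mm
#' @param seed integer; trial t uses seed `seed + t - 1`
#' @param n_steps servo steps per trial
#' @param source_depth tip depth, mm
#' @param config,geom,seg_params,n_samples,f_number loop settings
#' @return data.frame with one row per trial: initial offset, final
#'   `d_p` (mm), success flag, final mode, seed
#' @export
run_centering_experiment <- function(preset, n_trials = 10L,
                                     initial_offset_range = 15,
                                     seed = 0L, n_steps = 22L,
                                     source_depth = 20,
                                     config = servo_config(),
                                     geom = transducer_geometry(),
                                     seg_params = segmentation_params(),
                                     n_samples = 1024L, f_number = 3.3) {
  medium <- .resolve_preset(preset)
  out <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    trial_seed <- as.integer(seed) + t - 1L
    offset <- withr::with_seed(trial_seed,
                               runif(1, -initial_offset_range,
                                     initial_offset_range))
    log <- run_servo_loop(c(0, 0, source_depth), medium, config,
                          n_steps = n_steps, seed = trial_seed,
                          geom = geom, seg_params = seg_params,
                          initial_probe = c(-offset, 0, 0),
                          n_samples = n_samples, f_number = f_number)
    last <- log$trajectory[nrow(log$trajectory), ]
    success <- log$final_mode == "TRACKING" && isTRUE(last$found)
    out[[t]] <- data.frame(trial = t,
                           initial_offset_mm = offset,
                           d_p_mm = if (success) abs(last$d_p_mm) else NA_real_,
                           success = success,
                           final_mode = log$final_mode,
                           tissue = medium$name, seed = trial_seed)
  }
  do.call(rbind, out)
}

#' Angled-insertion and perturbation-recovery experiment
#'
#' The needle advances 13 mm along a line at the given angle to the probe
#' lateral axis (elevation drift = advance * sin(angle)), spread over the
#' first `insertion_steps` servo steps, while the loop tracks and centers
#' the probe. At nonzero angles the tip drifts out of the elevation beam,
#' forcing SEARCHING episodes that the back-and-forth scan must resolve.
#' With `perturb = TRUE`, one or two scripted probe displacements are
#' injected mid-insertion. A trial succeeds when tip visualization is
#' maintained or recovered throughout (final mode TRACKING with a final
#' detection); a search timeout is a failure.
#'
#' @param angles degrees; trials cycle through these
#' @param n_trials total trials (default 10: each angle twice)
#' @param perturb inject scripted perturbations?
#' @param preset a [tissue_preset()] or preset name (default liver)
#' @param seed integer; trial t uses seed `seed + t - 1`
#' @param insertion_mm total needle advance, mm
#' @param insertion_steps servo steps over which the advance happens
#' @param n_steps total servo steps per trial
#' @param source_depth tip depth, mm
#' @param config,geom,seg_params,n_samples,f_number loop settings
#' @return data.frame with one row per trial: angle, success, number of
#'   SEARCHING episodes, mean |d_p| while tracking, final mode, seed
#' @export
run_angled_experiment <- function(angles = c(-20, -10, 0, 10, 20),
                                  n_trials = 10L, perturb = FALSE,
                                  preset = "liver", seed = 0L,
                                  insertion_mm = 13, insertion_steps = 40L,
                                  n_steps = 160L, source_depth = 20,
                                  config = servo_config(),
                                  geom = transducer_geometry(),
                                  seg_params = segmentation_params(),
                                  n_samples = 1024L, f_number = 3.3) {
  medium <- .resolve_preset(preset)
  out <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    angle <- angles[(t - 1) %% length(angles) + 1]
    trial_seed <- as.integer(seed) + t - 1L
    x0 <- -insertion_mm * cos(angle * pi / 180) / 2
    path <- function(step) {
      adv <- min(step, insertion_steps) / insertion_steps * insertion_mm
      c(x0 + adv * cos(angle * pi / 180),
        adv * sin(angle * pi / 180),
        source_depth)
    }
    pert <- NULL
    if (perturb) {
      pert <- data.frame(step = c(15L, 55L)[seq_len(1L + t %% 2L)],
                         dx = 0, dy = 8, dz = 0)
    }
    log <- run_servo_loop(path, medium, config, n_steps = n_steps,
                          seed = trial_seed, geom = geom,
                          seg_params = seg_params,
                          initial_probe = c(x0, 0, 0),
                          perturbations = pert,
                          n_samples = n_samples, f_number = f_number)
    tr <- log$trajectory
    last <- tr[nrow(tr), ]
    searches <- sum(log$events$event == "mode" &
                      grepl("-> SEARCHING", log$events$detail))
    success <- log$final_mode == "TRACKING" && isTRUE(last$found)
    dp <- abs(tr$d_p_mm[tr$mode == "TRACKING" & tr$consensus])
    out[[t]] <- data.frame(trial = t, angle = angle, perturb = perturb,
                           success = success, searches = searches,
                           mean_dp_mm = if (length(dp)) mean(dp) else NA_real_,
                           final_mode = log$final_mode,
                           tissue = medium$name, seed = trial_seed)
  }
  do.call(rbind, out)
}

#' Fluence sweep: image quality versus laser energy
#'
#' For each (preset, energy) pair, `n_acq` seeded acquisitions are taken
#' of a stationary tip; contrast and SNR are measured in the beamformed
#' envelope image (target region at the known tip, background at the same
#' depth rows away from it), channel SNR in the raw data with the default
#' gates, and the tip is segmented to record a detection fraction.
#' Means and population standard deviations over the acquisitions are
#' reported. The fluence column is `energy_to_fluence()` exactly.
#'
#' @param presets character vector of preset names
#' @param energies mJ (defaults span 0.3-3.4 mJ and include 1.58 mJ)
#' @param n_acq acquisitions per condition (default 10)
#' @param seed integer seed
#' @param source_depth tip depth, mm
#' @param geom,seg_params,n_samples,f_number acquisition settings
#' @return data.frame with one row per (preset, energy)
#' @export
run_fluence_sweep <- function(presets = c("water", "chicken_thigh",
                                          "chicken_thigh_clutter"),
                              energies = c(0.3, 0.65, 1, 1.58, 2, 2.75, 3.4),
                              n_acq = 10L, seed = 1L, source_depth = 20,
                              geom = transducer_geometry(),
                              seg_params = segmentation_params(),
                              n_samples = 1024L, f_number = 3.3) {
  stopifnot(all(energies > 0))
  rows <- list()
  for (pname in presets) {
    medium <- .resolve_preset(pname)
    grid <- experiment_grid(geom, medium$sound_speed)
    src0 <- fiber_source(c(0, 0, source_depth))
    roi <- .tip_rois(grid, lateral = 0, depth = source_depth)
    gates <- default_snr_gates(src0, geom, medium, n_samples = n_samples)
    for (e in energies) {
      src <- fiber_source(c(0, 0, source_depth), pulse_energy = e)
      cvals <- svals <- chvals <- numeric(n_acq)
      det <- logical(n_acq)
      for (a in seq_len(n_acq)) {
        acq_seed <- (as.integer(seed) * 10007L + a * 7919L +
                       match(pname, presets) * 53L +
                       which(energies == e)[1] * 17L) %% 2147483647L
        frame <- simulate_channel_frame(src, geom, medium, seed = acq_seed,
                                        n_samples = n_samples)
        rf <- das_beamform(frame, geom, grid, medium$sound_speed, f_number)
        img <- pa_image(envelope_detect(rf), grid)
        cvals[a] <- tryCatch(contrast(img, roi$inside, roi$outside),
                             error = function(e) NA_real_)
        svals[a] <- tryCatch(snr_image(img, roi$inside, roi$outside),
                             error = function(e) NA_real_)
        chvals[a] <- tryCatch(channel_snr(frame, gates$signal_gate,
                                          gates$noise_gate),
                              error = function(e) NA_real_)
        det[a] <- segment_frame(img, seg_params)$found
      }
      rows[[length(rows) + 1]] <- data.frame(
        preset = pname, energy_mj = e,
        fluence_mj_cm2 = energy_to_fluence(e, src$core_diameter),
        contrast_db = mean(cvals), contrast_sd = .pop_sd(cvals),
        snr = mean(svals), snr_sd = .pop_sd(svals),
        channel_snr = mean(chvals), channel_snr_sd = .pop_sd(chvals),
        detected_frac = mean(det))
    }
  }
  do.call(rbind, rows)
}

# target/background regions at the same depth rows for contrast and SNR
.tip_rois <- function(grid, lateral, depth, half_ax = 1, half_lat = 1.5,
                      bg_offset = 8, bg_width = 10) {
  lat <- grid_lateral(grid)
  ax <- grid_axial(grid)
  rows <- which(abs(ax - depth) <= half_ax)
  in_cols <- which(abs(lat - lateral) <= half_lat)
  out_cols <- which(lat - lateral >= bg_offset &
                      lat - lateral <= bg_offset + bg_width)
  if (!length(out_cols))
    out_cols <- which(lat - lateral <= -bg_offset &
                        lat - lateral >= -(bg_offset + bg_width))
  list(inside = as.matrix(expand.grid(row = rows, col = in_cols)),
       outside = as.matrix(expand.grid(row = rows, col = out_cols)))
}
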