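#' Probe-to-robot calibration
#'
#' Wraps the rigid transform from the probe image frame to the robot
#' end-effector frame, obtained externally. Validated as a proper rigid
#' transform on construction.
#'
#' @param F_cal 4x4 rigid transform
#' @return an object of class `calibration`
#' @export
calibration <- function(F_cal = diag(4)) {
  .check_rigid(F_cal, "F_cal")
  structure(list(F_cal = F_cal), class = "calibration")
}

#' Robot end-effector state
#'
#' @param F_robot 4x4 rigid transform, end effector to robot base
#' @return an object of class `robot_state`
#' @export
robot_state <- function(F_robot = diag(4)) {
  .check_rigid(F_robot, "F_robot")
  structure(list(F_robot = F_robot), class = "robot_state")
}

#' Servo-loop configuration
#'
#' `failure_threshold` consecutive consensus failures switch the
#' controller from TRACKING to SEARCHING; the search scans the probe back
#' and forth along its elevation axis over a total span of `scan_span`
#' (default 60 mm, i.e. +/- 30 mm about the pose where the tip was lost)
#' in increments of `scan_step`, giving up after `timeout` search steps.
#' While tracking, the probe moves by `gain` times the centering offset,
#' clamped to `max_step` per step.
#'
#' @param failure_threshold frames (default 5)
#' @param scan_span total back-and-forth sweep, mm (default 60)
#' @param scan_step mm per search step
#' @param timeout maximum search steps before giving up
#' @param max_step largest commanded translation per step, mm
#' @param gain proportional gain in (0, 1]
#' @return an object of class `servo_config`
#' @export
servo_config <- function(failure_threshold = 5L, scan_span = 60,
                         scan_step = 3, timeout = 60L, max_step = 2,
                         gain = 1) {
  stopifnot(failure_threshold >= 1, scan_span > 0, scan_step > 0,
            timeout > 0, max_step > 0, gain > 0, gain <= 1)
  structure(list(failure_threshold = as.integer(failure_threshold),
                 scan_span = scan_span, scan_step = scan_step,
                 timeout = as.integer(timeout), max_step = max_step,
                 gain = gain),
            class = "servo_config")
}

#' Centering vector from the consensus tip location
#'
#' The vector from the center of the top row of the image (lateral 0,
#' depth `z_min`) to `p_bar`. Its lateral component is what drives the
#' probe-centering motion.
#'
#' @param p_bar c(lateral, axial) in image-frame mm
#' @param grid an [image_grid()]
#' @return c(lateral, axial) centering vector, mm
#' @export
image_to_centering_vector <- function(p_bar, grid) {
  c(lateral = unname(p_bar[1]), axial = unname(p_bar[2]) - grid$z_min)
}

#' Map a lateral centering offset into robot-base coordinates
#'
#' Embeds the scalar lateral component as a displacement vector along the
#' image lateral axis and applies the rotation parts of the calibration
#' and robot transforms (`p_robot = R_robot R_cal (x, 0, 0)`);
#' translations do not apply to displacement vectors.
#'
#' @param p_center_x lateral centering component, mm
#' @param cal a [calibration()]
#' @param robot a [robot_state()]
#' @return length-3 displacement in the robot base frame, mm
#' @export
map_to_robot <- function(p_center_x, cal = calibration(),
                         robot = robot_state()) {
  stopifnot(inherits(cal, "calibration"), inherits(robot, "robot_state"))
  v <- c(p_center_x, 0, 0)
  as.numeric(robot$F_robot[1:3, 1:3] %*% (cal$F_cal[1:3, 1:3] %*% v))
}

#' Proportional motion command with step clamping
#'
#' `command = clamp(gain * p_robot, max_step)`: a proportional step
#' toward the target, never longer than `max_step`. Applying the command
#' reduces `|p_robot|` for any gain in (0, 1].
#'
#' @param p_robot length-3 displacement toward the target, mm
#' @param config a [servo_config()]
#' @return length-3 commanded probe translation, mm
#' @export
step_controller <- function(p_robot, config = servo_config()) {
  cmd <- config$gain * p_robot
  n <- sqrt(sum(cmd^2))
  if (n > config$max_step) cmd <- cmd * config$max_step / n
  cmd
}

#' Triangle-wave search offset
#'
#' Elevation offset from the scan center after `i` search steps:
#' back-and-forth over `[-scan_span/2, +scan_span/2]`, advancing
#' `scan_step` per step, starting toward positive elevation. The visited
#' positions over a full sweep span exactly `scan_span`.
#'
#' @param i search step counter (0 = scan center)
#' @param config a [servo_config()]
#' @return elevation offset, mm
#' @export
scan_offset <- function(i, config = servo_config()) {
  half <- config$scan_span / 2
  u <- (i * config$scan_step) %% (2 * config$scan_span)
  ifelse(u <= half, u,
         ifelse(u <= 3 * half, half - (u - half),
                u - 2 * config$scan_span))
}

#' Displace the probe (perturbation injection)
#'
#' Models a patient- or operator-induced probe displacement: the probe
#' pose is shifted by `offset` (world frame, mm) and the event is
#' logged. If the displacement takes the tip out of the elevation beam,
#' subsequent consensus fails and the search behavior engages.
#'
#' @param state a `servo_state` (see [run_servo_loop()])
#' @param offset length-3 world displacement, mm
#' @return the updated state
#' @export
apply_perturbation <- function(state, offset) {
  stopifnot(length(offset) == 3)
  state$probe <- state$probe + as.numeric(offset)
  state$events <- rbind(state$events,
                        data.frame(step = state$step, event = "perturbation",
                                   detail = sprintf("offset (%g, %g, %g) mm",
                                                    offset[1], offset[2],
                                                    offset[3])))
  state
}

.allowed_transitions <- rbind(c("TRACKING", "SEARCHING"),
                              c("SEARCHING", "TRACKING"),
                              c("SEARCHING", "TIMEOUT"))

.transition <- function(state, to) {
  from <- state$mode
  ok <- any(.allowed_transitions[, 1] == from & .allowed_transitions[, 2] == to)
  if (!ok) stop("forbidden servo transition ", from, " -> ", to)
  state$mode <- to
  state$events <- rbind(state$events,
                        data.frame(step = state$step, event = "mode",
                                   detail = paste(from, "->", to)))
  state
}

#' Run the closed-loop visual-servoing simulation
#'
#' Per step: simulate a channel frame at the current probe pose, beamform
#' and envelope-detect it, segment the tip, and update the five-frame
#' consensus. While TRACKING, a consensus tip location is converted to a
#' centering vector, mapped through the calibration into robot
#' coordinates, and a clamped proportional translation is applied to the
#' probe; `failure_threshold` consecutive consensus failures switch to
#' SEARCHING, which steps the probe along a triangle wave in elevation
#' until a single-frame detection returns control to TRACKING or the
#' search times out (TIMEOUT, terminal). Detections are compared for
#' spatial consistency in the world frame (image position plus probe
#' position), so a stationary tip remains consistent while the probe
#' moves.
#'
#' @param source_path function(step) returning the world tip position
#'   c(x, y, z) at that step, or a fixed length-3 vector
#' @param medium a [tissue_preset()]
#' @param config a [servo_config()]
#' @param n_steps number of servo steps
#' @param seed integer seed controlling all randomness in the run
#' @param geom a [transducer_geometry()]
#' @param grid an [image_grid()] (default built from `geom` and the
#'   medium sound speed)
#' @param seg_params a [segmentation_params()]
#' @param cal,robot calibration and robot transforms
#' @param initial_probe world probe position c(x, y, z) at step 1
#' @param pulse_energy source pulse energy, mJ
#' @param source_depth depth used when `source_path` returns only x/y
#' @param perturbations optional data.frame(step, dx, dy, dz) of scripted
#'   probe displacements applied before the given step
#' @param n_samples channel samples per frame
#' @param f_number receive F-number
#' @return an object of class `servo_log`: list(trajectory = data.frame
#'   (step, mode, probe_x, probe_y, probe_z, found, d_p_mm, consensus),
#'   events = data.frame(step, event, detail), final_mode, state)
#' @export
run_servo_loop <- function(source_path, medium, config = servo_config(),
                           n_steps = 30L, seed = 1L,
                           geom = transducer_geometry(),
                           grid = experiment_grid(geom, medium$sound_speed),
                           seg_params = segmentation_params(),
                           cal = calibration(), robot = robot_state(),
                           initial_probe = c(0, 0, 0),
                           pulse_energy = 2.75,
                           perturbations = NULL,
                           n_samples = 1024L, f_number = 3.3) {
  if (is.numeric(source_path)) {
    fixed <- as.numeric(source_path)
    source_path <- function(step) fixed
  }
  state <- list(mode = "TRACKING", probe = as.numeric(initial_probe),
                step = 0L,
                history = detection_history(seg_params$history_length),
                scan_center = NA_real_, scan_i = 0L,
                events = data.frame(step = integer(), event = character(),
                                    detail = character()))
  traj <- vector("list", n_steps)
  for (step in seq_len(n_steps)) {
    state$step <- step
    if (!is.null(perturbations)) {
      hit <- which(perturbations$step == step)
      for (h in hit) {
        state <- apply_perturbation(state, c(perturbations$dx[h],
                                             perturbations$dy[h],
                                             perturbations$dz[h]))
        if (state$mode == "SEARCHING") state$scan_center <- state$probe[2]
      }
    }
    tip_world <- source_path(step)
    pose <- probe_pose(state$probe)
    src <- fiber_source(tip_world, pulse_energy = pulse_energy)
    step_seed <- (seed * 10007L + step * 7919L) %% 2147483647L
    img <- acquire_image(src, geom, medium, grid, pose, seed = step_seed,
                         n_samples = n_samples, f_number = f_number,
                         frame_index = step)
    det <- segment_frame(img, seg_params)
    d_p <- if (det$found) unname(det$tip_mm[1]) else NA_real_
    det_world <- det
    if (det$found) {
      # express in world frame for spatial-consistency checks
      det_world$tip_mm <- c(lateral = state$probe[1] + det$tip_mm[[1]],
                            axial = det$tip_mm[[2]])
    }
    consensus <- FALSE
    if (state$mode == "TRACKING") {
      state$history <- history_push(state$history, det_world)
      res <- temporal_consensus(state$history, seg_params)
      state$history <- res$history
      if (!is.null(res$p_bar)) {
        consensus <- TRUE
        p_img <- c(res$p_bar[1] - state$probe[1], res$p_bar[2])
        p_center <- image_to_centering_vector(p_img, grid)
        p_rob <- map_to_robot(p_center[1], cal, robot)
        cmd <- step_controller(p_rob, config)
        state$probe <- state$probe + cmd
      } else if (state$history$consecutive_failures >=
                 config$failure_threshold) {
        state <- .transition(state, "SEARCHING")
        state$scan_center <- state$probe[2]
        state$scan_i <- 0L
        state$history <- detection_history(seg_params$history_length)
      }
    } else if (state$mode == "SEARCHING") {
      if (det$found) {
        # hold the scan position and require consensus-grade confirmation
        # before resuming tracking; an isolated false detection fails the
        # confirmation and the scan continues
        state$history <- history_push(state$history, det_world)
        res <- temporal_consensus(state$history, seg_params)
        state$history <- res$history
        if (!is.null(res$p_bar)) {
          state <- .transition(state, "TRACKING")
          state$scan_i <- 0L
        }
      } else {
        state$history <- detection_history(seg_params$history_length)
        if (state$scan_i >= config$timeout) {
          state <- .transition(state, "TIMEOUT")
        } else {
          state$scan_i <- state$scan_i + 1L
          state$probe[2] <- state$scan_center +
            scan_offset(state$scan_i, config)
        }
      }
    }
    traj[[step]] <- data.frame(step = step, mode = state$mode,
                               probe_x = state$probe[1],
                               probe_y = state$probe[2],
                               probe_z = state$probe[3],
                               found = det$found, d_p_mm = d_p,
                               consensus = consensus)
    if (state$mode == "TIMEOUT") break
  }
  trajectory <- do.call(rbind, traj[!vapply(traj, is.null, TRUE)])
  structure(list(trajectory = trajectory, events = state$events,
                 final_mode = state$mode, state = state),
            class = "servo_log")
}

#' @export
print.servo_log <- function(x, ...) {
  cat(sprintf("<servo_log> %d steps, final mode %s, %d events\n",
              nrow(x$trajectory), x$final_mode, nrow(x$events)))
  invisible(x)
}
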