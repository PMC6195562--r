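# Persistence: channel frames as raw float32 binary with a JSON sidecar,
# configuration objects as YAML, display images as 8-bit PNG.

#' Write a channel frame to disk
#'
#' Samples are stored column-major as little-endian float32 in
#' `<path>.bin`; dimensions, sampling frequency and frame index go to the
#' JSON sidecar `<path>.json`.
#'
#' @param frame a `channel_frame`
#' @param path file path without extension
#' @return `path`, invisibly
#' @export
write_channel_frame <- function(frame, path) {
  stopifnot(inherits(frame, "channel_frame"))
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(frame$samples), con, size = 4, endian = "little")
  jsonlite::write_json(list(n_samples = nrow(frame$samples),
                            n_elements = ncol(frame$samples),
                            sampling_frequency = frame$sampling_frequency,
                            frame_index = frame$frame_index,
                            dtype = "float32le"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a channel frame written by [write_channel_frame()]
#' @param path file path without extension
#' @return a `channel_frame`
#' @export
read_channel_frame <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$n_samples * meta$n_elements
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = n, size = 4, endian = "little")
  structure(list(samples = matrix(v, meta$n_samples, meta$n_elements),
                 sampling_frequency = meta$sampling_frequency,
                 frame_index = as.integer(meta$frame_index)),
            class = "channel_frame")
}

#' Write a log-compressed image as 8-bit PNG
#'
#' Optionally also writes the linear envelope as float32 binary with a
#' JSON sidecar describing the grid (for quantitative reuse).
#'
#' @param image a `pa_image`
#' @param path output file (.png)
#' @param dynamic_range dB
#' @param envelope_path optional path (without extension) for the
#'   float32 envelope + JSON sidecar
#' @return `path`, invisibly
#' @export
write_pa_image <- function(image, path, dynamic_range = 30,
                           envelope_path = NULL) {
  db <- log_compress(image, dynamic_range)
  png::writePNG((db + dynamic_range) / dynamic_range, path)
  if (!is.null(envelope_path)) {
    con <- file(paste0(envelope_path, ".bin"), "wb")
    on.exit(close(con))
    writeBin(as.numeric(image$envelope), con, size = 4, endian = "little")
    jsonlite::write_json(c(list(dtype = "float32le"),
                           unclass(image$grid)),
                         paste0(envelope_path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Write geometry/medium/servo configuration to YAML
#' @param config a list or one of the package's configuration objects
#' @param path output file (.yaml)
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a YAML configuration written by [write_config()]
#'
#' @param path YAML file
#' @param as optional class to restore: one of "transducer_geometry",
#'   "medium_preset", "segmentation_params", "servo_config"
#' @return a list, classed when `as` is given
#' @export
read_config <- function(path, as = NULL) {
  x <- yaml::read_yaml(path)
  if (!is.null(as)) {
    ctor <- switch(as,
                   transducer_geometry = transducer_geometry,
                   medium_preset = function(...) {
                     structure(list(...), class = "medium_preset")
                   },
                   segmentation_params = segmentation_params,
                   servo_config = servo_config,
                   stop("unknown config class: ", as))
    x <- do.call(ctor, x)
  }
  x
}

#' Append per-frame detections to a CSV log
#'
#' Columns: frame_index, found, row, col, lateral_mm, axial_mm, area.
#'
#' @param detections list of `tip_detection` objects
#' @param path CSV file (created with a header if absent)
#' @param frame_index integer vector parallel to `detections`
#' @return `path`, invisibly
#' @export
write_detection_log <- function(detections, path,
                                frame_index = seq_along(detections)) {
  rows <- do.call(rbind, lapply(seq_along(detections), function(i) {
    d <- detections[[i]]
    data.frame(frame_index = frame_index[i], found = d$found,
               row = d$tip_pixel[1], col = d$tip_pixel[2],
               lateral_mm = d$tip_mm[1], axial_mm = d$tip_mm[2],
               area = d$label_area)
  }))
  write.table(rows, path, sep = ",", row.names = FALSE,
              col.names = !file.exists(path), append = file.exists(path))
  invisible(path)
}

#' Write a servo trajectory log as CSV and its events as JSON
#'
#' @param log a `servo_log` from [run_servo_loop()]
#' @param path_prefix files `<prefix>_trajectory.csv` and
#'   `<prefix>_events.json` are written
#' @return `path_prefix`, invisibly
#' @export
write_servo_log <- function(log, path_prefix) {
  write.csv(log$trajectory, paste0(path_prefix, "_trajectory.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(final_mode = log$final_mode,
                            events = log$events),
                       paste0(path_prefix, "_events.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path_prefix)
}
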