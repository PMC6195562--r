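#' Segmentation parameters
#'
#' Controls the needle-tip segmentation pipeline. The binary threshold is
#' dynamic: `threshold_fraction` of the current frame's envelope maximum
#' (0.5 by default, the half-maximum convention also used for resolution
#' measurements). Opening with a disk of radius `struct_elem_radius`
#' removes single-pixel regions; connected components are labeled with
#' the given connectivity; the tip label must be the largest-area label
#' *and* an upper-Tukey-fence outlier (Q3 + `outlier_rule` * IQR over the
#' label-area histogram, quartiles by linear interpolation of order
#' statistics) and at least `min_area` pixels. The temporal consensus
#' requires `history_length` consecutive detections within
#' `consistency_radius` of each other.
#'
#' @param threshold_fraction fraction of the frame maximum, in (0, 1)
#' @param struct_elem_radius structuring-element radius, pixels
#' @param connectivity 4 or 8
#' @param outlier_rule Tukey fence multiplier
#' @param min_area minimum tip area, pixels
#' @param history_length consensus buffer length, frames
#' @param consistency_radius maximum pairwise distance between buffered
#'   detections, mm (default 2 mm, the lateral resolution)
#' @return an object of class `segmentation_params`
#' @export
segmentation_params <- function(threshold_fraction = 0.5,
                                struct_elem_radius = 1L,
                                connectivity = 8L,
                                outlier_rule = 1.5,
                                min_area = 20L,
                                history_length = 5L,
                                consistency_radius = 2) {
  stopifnot(threshold_fraction > 0, threshold_fraction < 1,
            struct_elem_radius >= 0, connectivity %in% c(4L, 8L),
            outlier_rule > 0, min_area >= 1,
            history_length >= 1, consistency_radius > 0)
  structure(list(threshold_fraction = threshold_fraction,
                 struct_elem_radius = as.integer(struct_elem_radius),
                 connectivity = as.integer(connectivity),
                 outlier_rule = outlier_rule,
                 min_area = as.integer(min_area),
                 history_length = as.integer(history_length),
                 consistency_radius = consistency_radius),
            class = "segmentation_params")
}

#' Dynamic binary thresholding
#'
#' Mask of pixels at or above `threshold_fraction` times the frame
#' maximum of the (linear, pre-log) envelope.
#'
#' @param image a `pa_image` or envelope matrix
#' @param params a [segmentation_params()]
#' @return logical matrix
#' @export
threshold_binary <- function(image, params = segmentation_params()) {
  env <- if (inherits(image, "pa_image")) image$envelope else as.matrix(image)
  m <- max(env)
  if (m <= 0) stop("cannot threshold an all-zero image")
  env >= params$threshold_fraction * m
}

#' Morphological opening of a binary mask
#'
#' Binary erosion followed by dilation with a disk (diamond) structuring
#' element, removing isolated single-pixel regions for radius >= 1 while
#' preserving solid blobs. Radius 0 is a no-op.
#'
#' @param mask logical matrix
#' @param struct_elem_radius disk radius, pixels
#' @return logical matrix
#' @export
morph_clean <- function(mask, struct_elem_radius = 1L) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  storage.mode(mask) <- "logical"
  if (struct_elem_radius < 1 || !any(mask)) return(mask)
  r <- as.integer(struct_elem_radius)
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "diamond")
  # pad with background so pixels outside the image never support a
  # foreground pixel (scipy-style border_value = 0)
  nr <- nrow(mask)
  nc <- ncol(mask)
  padded <- matrix(0, nr + 2L * r, nc + 2L * r)
  padded[r + seq_len(nr), r + seq_len(nc)] <- as.numeric(mask)
  opened <- EBImage::dilate(EBImage::erode(padded, brush), brush)
  matrix(as.numeric(opened[r + seq_len(nr), r + seq_len(nc)]) > 0.5, nr, nc)
}

#' Connected-component labeling
#'
#' Labels maximal connected regions of a binary mask under 4- or
#' 8-connectivity. Labels are positive integers; background is 0.
#'
#' @param mask logical matrix
#' @param connectivity 4 or 8
#' @return list(labels = integer matrix, areas = named integer vector of
#'   pixel counts per label)
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)),
            connectivity %in% c(4L, 8L))
  storage.mode(mask) <- "logical"
  lab <- label_core(mask, as.integer(connectivity))
  n <- attr(lab, "n_labels")
  areas <- if (n > 0) tabulate(lab[lab > 0], nbins = n) else integer(0)
  names(areas) <- if (n > 0) as.character(seq_len(n)) else character(0)
  list(labels = lab, areas = areas)
}

#' Select the needle-tip label from the area histogram
#'
#' The tip is the label with the largest area, accepted only if that area
#' is a distinct outlier of the area histogram: above the upper Tukey
#' fence `Q3 + outlier_rule * IQR` (quartiles by linear interpolation of
#' order statistics) and at least `min_area`. The fence needs at least
#' four areas to be meaningful: a single label is accepted whenever it
#' meets `min_area`, and with two or three labels the largest is accepted
#' when it dominates (at least twice the second-largest area). Ties for
#' the largest area mean there is no distinct outlier. Returns `NA` when
#' no label qualifies (tip not visible).
#'
#' @param areas integer vector of label areas (possibly empty)
#' @param params a [segmentation_params()]
#' @return the selected label index (into `areas`), or `NA_integer_`
#' @export
select_tip_label <- function(areas, params = segmentation_params()) {
  if (!length(areas)) return(NA_integer_)
  imax <- which.max(areas)
  if (areas[imax] < params$min_area) return(NA_integer_)
  if (length(areas) == 1L) return(1L)
  if (sum(areas == areas[imax]) > 1L) return(NA_integer_)
  if (length(areas) < 4L) {
    second <- max(areas[-imax])
    return(if (areas[imax] >= 2 * second) as.integer(imax) else NA_integer_)
  }
  q <- quantile(as.numeric(areas), c(0.25, 0.75), names = FALSE, type = 7)
  fence <- q[2] + params$outlier_rule * (q[2] - q[1])
  if (areas[imax] > fence) as.integer(imax) else NA_integer_
}

#' Centroid of a labeled region
#'
#' Unweighted mean of the member pixel coordinates.
#'
#' @param labels integer label matrix from [label_components()]
#' @param label label number
#' @return c(row, col), continuous 1-based pixel coordinates
#' @export
region_centroid <- function(labels, label) {
  idx <- which(labels == label, arr.ind = TRUE)
  if (!nrow(idx)) stop("label ", label, " not present")
  c(row = mean(idx[, 1]), col = mean(idx[, 2]))
}

#' Segment the needle tip in one frame
#'
#' Runs the full per-frame pipeline: dynamic thresholding, morphological
#' opening, connected-component labeling, outlier-based tip-label
#' selection, and centroid extraction converted to image-frame mm.
#' Reflection artifacts (smaller, dimmer blobs below the tip) are
#' rejected by the threshold and the outlier rule. An image with no
#' qualifying blob - including an all-zero image - yields
#' `found = FALSE`, not an error.
#'
#' @param image a [pa_image()]
#' @param params a [segmentation_params()]
#' @return an object of class `tip_detection`: list(found, tip_pixel,
#'   tip_mm, label_area)
#' @export
segment_frame <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "pa_image"))
  none <- structure(list(found = FALSE, tip_pixel = c(NA_real_, NA_real_),
                         tip_mm = c(NA_real_, NA_real_), label_area = 0L),
                    class = "tip_detection")
  if (max(image$envelope) <= 0) return(none)
  mask <- threshold_binary(image, params)
  mask <- morph_clean(mask, params$struct_elem_radius)
  comp <- label_components(mask, params$connectivity)
  sel <- select_tip_label(comp$areas, params)
  if (is.na(sel)) return(none)
  ctr <- region_centroid(comp$labels, sel)
  structure(list(found = TRUE, tip_pixel = ctr,
                 tip_mm = pixel_to_mm(image$grid, ctr[1], ctr[2]),
                 label_area = unname(comp$areas[sel])),
            class = "tip_detection")
}

#' @export
print.tip_detection <- function(x, ...) {
  if (x$found)
    cat(sprintf("<tip_detection> found at (%.2f, %.2f) mm, area %d px\n",
                x$tip_mm[1], x$tip_mm[2], x$label_area))
  else cat("<tip_detection> not found\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Detection history and temporal consensus

#' Create an empty detection history
#'
#' Ring buffer of the most recent per-frame detections (including the
#' current frame) plus a consecutive-failure counter.
#'
#' @param history_length buffer capacity, frames
#' @return an object of class `detection_history`
#' @export
detection_history <- function(history_length = 5L) {
  structure(list(detections = list(),
                 history_length = as.integer(history_length),
                 consecutive_failures = 0L),
            class = "detection_history")
}

#' Append a detection to the history
#'
#' @param history a [detection_history()]
#' @param detection a `tip_detection`; `tip_mm` may have been re-expressed
#'   in a common (world) frame by the caller before pushing
#' @return the updated history
#' @export
history_push <- function(history, detection) {
  history$detections <- c(history$detections, list(detection))
  extra <- length(history$detections) - history$history_length
  if (extra > 0) history$detections <- history$detections[-seq_len(extra)]
  history
}

#' Spatiotemporal consensus over the detection buffer
#'
#' If the buffer holds `history_length` detections, all found, and all
#' pairwise distances are within `consistency_radius`, the detections are
#' averaged into the most likely tip location `p_bar` and the failure
#' counter resets. Otherwise no consensus is reported and the
#' consecutive-failure counter increments.
#'
#' @param history a [detection_history()]
#' @param params a [segmentation_params()]
#' @return list(p_bar = c(lateral, axial) mm or NULL, history = updated
#'   history)
#' @export
temporal_consensus <- function(history, params = segmentation_params()) {
  dets <- history$detections
  ok <- length(dets) >= params$history_length &&
    all(vapply(dets, function(d) isTRUE(d$found), TRUE))
  if (ok) {
    pts <- do.call(rbind, lapply(dets, function(d) d$tip_mm))
    dmat <- as.matrix(stats::dist(pts))
    ok <- max(dmat) <= params$consistency_radius
  }
  if (ok) {
    history$consecutive_failures <- 0L
    list(p_bar = colMeans(pts), history = history)
  } else {
    history$consecutive_failures <- history$consecutive_failures + 1L
    list(p_bar = NULL, history = history)
  }
}
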