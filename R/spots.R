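#' Detect printed spots in the tracer channel
#'
#' Thresholds the tracer image (Otsu by default), labels connected
#' components, fills holes, and keeps components whose equivalent diameter
#' (`2 * sqrt(area / pi) * um_per_pixel`) falls inside the diameter window.
#' The window default brackets the nominal 300 micrometre spot. Detections
#' are returned sorted row-major by centroid.
#'
#' @param tracer numeric intensity matrix (tracer / ~560 nm channel).
#' @param um_per_pixel pixel scale.
#' @param min_diameter,max_diameter accepted equivalent-diameter window,
#'   micrometres.
#' @param threshold `"otsu"` or a fixed numeric threshold; pixels strictly
#'   above threshold are foreground.
#' @return data frame of class `spot_detections`: `detection_id`, `x_px`,
#'   `y_px` (0-based centroid, column/row), `area_px`,
#'   `equivalent_diameter_um`, `mean_tracer_intensity`, `matched_spot_id`
#'   (`NA` until [register_to_layout()]).
#' @export
detect_spots <- function(tracer, um_per_pixel, min_diameter = 150,
                         max_diameter = 600, threshold = "otsu") {
  stopifnot(is.matrix(tracer), length(tracer) > 0)
  if (min_diameter >= max_diameter)
    stop_pa("min_diameter must be below max_diameter",
            class = "phenoarray_bad_arg")
  if (is.character(threshold)) {
    if (!identical(threshold, "otsu"))
      stop_pa("unknown threshold strategy '%s'", threshold,
              class = "phenoarray_bad_threshold")
    thr <- otsu_threshold(tracer)
  } else if (is.numeric(threshold) && length(threshold) == 1L) {
    thr <- threshold
  } else {
    stop_pa("threshold must be 'otsu' or a single number",
            class = "phenoarray_bad_threshold")
  }
  mask <- fill_holes(tracer > thr)
  if (identical(threshold, "otsu") && !has_contrast(tracer, mask))
    mask[] <- FALSE
  labels <- label_components(mask)
  props <- region_props(labels, tracer)
  props$equivalent_diameter_um <-
    2 * sqrt(props$area_px / pi) * um_per_pixel
  keep <- props$equivalent_diameter_um >= min_diameter &
    props$equivalent_diameter_um <= max_diameter
  props <- props[keep, , drop = FALSE]
  props <- props[order(round(props$row), props$col), , drop = FALSE]
  out <- data.frame(
    detection_id = seq_len(nrow(props)),
    x_px = props$col - 1, y_px = props$row - 1,
    area_px = props$area_px,
    equivalent_diameter_um = props$equivalent_diameter_um,
    mean_tracer_intensity = props$mean_intensity,
    matched_spot_id = rep(NA_integer_, nrow(props)),
    stringsAsFactors = FALSE)
  class(out) <- c("spot_detections", "data.frame")
  out
}

#' Register spot detections to the expected grid layout
#'
#' Estimates a global translation between detections and the expected spot
#' centres as the median of per-detection offsets to the nearest expected
#' centre, then matches detections to spots one-to-one, greedily by
#' distance (nearest pair first), within `max_displacement`. If two
#' detections claim the same spot the farther one is left unmatched (and
#' reported). Rotation is not estimated.
#'
#' @param detections a [detect_spots()] result.
#' @param layout a [plan_grid()] layout.
#' @param field_origin `c(x, y)` micrometre offset of the field into the
#'   slide frame.
#' @param um_per_pixel pixel scale of the detection image.
#' @param max_displacement maximum allowed residual distance (micrometres)
#'   between a detection and its spot after translation.
#' @return the detections with `matched_spot_id` filled in, plus attributes
#'   `translation_um` (estimated `c(dx, dy)`) and `unmatched` (detection
#'   ids left unmatched).
#' @export
register_to_layout <- function(detections, layout, field_origin,
                               um_per_pixel, max_displacement = 100) {
  sp <- layout$spots
  if (nrow(detections) == 0L) {
    attr(detections, "translation_um") <- c(0, 0)
    attr(detections, "unmatched") <- integer()
    return(detections)
  }
  det_x <- px_center_um(detections$x_px + 1, field_origin[1L],
                        um_per_pixel)
  det_y <- px_center_um(detections$y_px + 1, field_origin[2L],
                        um_per_pixel)
  # offset to nearest expected centre, per detection
  off <- t(vapply(seq_along(det_x), function(i) {
    d2 <- (sp$center_x - det_x[i])^2 + (sp$center_y - det_y[i])^2
    j <- which.min(d2)
    c(det_x[i] - sp$center_x[j], det_y[i] - sp$center_y[j])
  }, numeric(2L)))
  translation <- c(median(off[, 1L]), median(off[, 2L]))
  adj_x <- det_x - translation[1L]
  adj_y <- det_y - translation[2L]
  # greedy nearest-first one-to-one matching within max_displacement
  pairs <- expand.grid(det = seq_along(adj_x), spot = seq_len(nrow(sp)))
  pairs$dist <- sqrt((adj_x[pairs$det] - sp$center_x[pairs$spot])^2 +
                     (adj_y[pairs$det] - sp$center_y[pairs$spot])^2)
  pairs <- pairs[pairs$dist <= max_displacement, , drop = FALSE]
  pairs <- pairs[order(pairs$dist), , drop = FALSE]
  matched_spot <- rep(NA_integer_, length(adj_x))
  spot_taken <- rep(FALSE, nrow(sp))
  for (k in seq_len(nrow(pairs))) {
    d <- pairs$det[k]; s <- pairs$spot[k]
    if (is.na(matched_spot[d]) && !spot_taken[s]) {
      matched_spot[d] <- sp$spot_id[s]
      spot_taken[s] <- TRUE
    }
  }
  detections$matched_spot_id <- matched_spot
  attr(detections, "translation_um") <- translation
  attr(detections, "unmatched") <-
    detections$detection_id[is.na(matched_spot)]
  detections
}
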