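#' Segment nuclei in the nuclear-stain channel
#'
#' Gaussian smoothing, Otsu (or fixed) thresholding, hole filling, then a
#' distance-transform watershed to split touching nuclei, followed by an
#' area filter. Cells are identified and counted from the resulting nucleus
#' mask; nuclei touching the field border are kept.
#'
#' @param nuclei numeric intensity matrix (nuclear channel, ~635 nm).
#' @param um_per_pixel pixel scale.
#' @param min_area,max_area accepted nucleus area window, square
#'   micrometres.
#' @param smooth_sigma_um Gaussian pre-smoothing sigma, micrometres.
#' @param marker_min_dist_um minimum separation between watershed seed
#'   maxima, micrometres; of the order of the nucleus radius.
#' @param threshold `"otsu"` or a fixed numeric value.
#' @return list with `labels` (integer label matrix) and `cells`, a data
#'   frame of `cell_records`: `cell_id`, `x_px`, `y_px` (0-based centroid),
#'   `area_px`, `area_um2`, `phenotype_intensity` (`NA` until
#'   [measure_phenotype()]), `expressing` (`NA` until
#'   [classify_expressing()]), `assigned_spot_id`.
#' @export
segment_nuclei <- function(nuclei, um_per_pixel, min_area = 30,
                           max_area = 500, smooth_sigma_um = 1.0,
                           marker_min_dist_um = 4, threshold = "otsu") {
  stopifnot(is.matrix(nuclei), length(nuclei) > 0)
  sm <- gaussian_blur(nuclei, smooth_sigma_um / um_per_pixel)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(sm) else
    as.numeric(threshold)
  mask <- fill_holes(sm > thr)
  empty <- list(labels = matrix(0L, nrow(nuclei), ncol(nuclei)),
                cells = empty_cell_records())
  if (!any(mask) ||
      (identical(threshold, "otsu") && !has_contrast(sm, mask)))
    return(empty)
  dist <- distance_transform(mask)
  # light smoothing of the distance map damps pixelization of the ridge
  dist_s <- gaussian_blur(dist, 0.5)
  dist_s[!mask] <- 0
  markers <- find_markers(dist_s, mask, marker_min_dist_um / um_per_pixel)
  if (!any(markers > 0L)) return(empty)
  labels <- watershed_regions(-dist_s, mask, markers)
  props <- region_props(labels)
  props$area_um2 <- props$area_px * um_per_pixel^2
  keep <- props$area_um2 >= min_area & props$area_um2 <= max_area
  props <- props[keep, , drop = FALSE]
  # relabel compactly, dropping filtered regions
  remap <- integer(max(labels))
  remap[props$label] <- seq_len(nrow(props))
  labels[labels > 0L] <- remap[labels[labels > 0L]]
  cells <- data.frame(
    cell_id = seq_len(nrow(props)),
    x_px = props$col - 1, y_px = props$row - 1,
    area_px = props$area_px, area_um2 = props$area_um2,
    phenotype_intensity = rep(NA_real_, nrow(props)),
    expressing = rep(NA, nrow(props)),
    assigned_spot_id = rep(NA_integer_, nrow(props)),
    stringsAsFactors = FALSE)
  class(cells) <- c("cell_records", "data.frame")
  list(labels = labels, cells = cells)
}

empty_cell_records <- function() {
  cells <- data.frame(cell_id = integer(), x_px = numeric(),
                      y_px = numeric(), area_px = integer(),
                      area_um2 = numeric(),
                      phenotype_intensity = numeric(),
                      expressing = logical(),
                      assigned_spot_id = integer(),
                      stringsAsFactors = FALSE)
  class(cells) <- c("cell_records", "data.frame")
  cells
}

#' Measure per-cell phenotype intensity
#'
#' For each cell, the mean phenotype intensity over its nucleus mask dilated
#' by `dilation_radius_um` (a bounded perinuclear region approximating the
#' whole-cell stain); dilated regions of neighbouring cells stay disjoint by
#' nearest-label assignment. `dilation_radius_um = 0` measures over the
#' nucleus mask exactly.
#'
#' @param cells a `cell_records` data frame from [segment_nuclei()].
#' @param labels the matching label matrix.
#' @param phenotype numeric intensity matrix (phenotype channel, ~488 nm),
#'   same shape as `labels`.
#' @param um_per_pixel pixel scale.
#' @param dilation_radius_um how far beyond the nucleus edge to measure.
#' @param statistic `"mean"` (intensity per pixel, the default) or
#'   `"total"` (integrated intensity over the region).
#' @return `cells` with `phenotype_intensity` filled in.
#' @export
measure_phenotype <- function(cells, labels, phenotype, um_per_pixel,
                              dilation_radius_um = 3,
                              statistic = c("mean", "total")) {
  statistic <- match.arg(statistic)
  if (!identical(dim(labels), dim(phenotype)))
    stop_pa("label grid (%d x %d) and phenotype grid (%d x %d) differ",
            nrow(labels), ncol(labels), nrow(phenotype), ncol(phenotype),
            class = "phenoarray_shape_mismatch")
  if (nrow(cells) == 0L) return(cells)
  region <- if (dilation_radius_um > 0)
    expand_labels(labels, dilation_radius_um / um_per_pixel) else labels
  idx <- which(region > 0L)
  lab <- region[idx]
  sums <- rowsum(as.numeric(phenotype[idx]), lab)
  counts <- tabulate(lab, nbins = max(lab))
  present <- as.integer(rownames(sums))
  value <- if (statistic == "mean")
    as.numeric(sums[, 1L]) / counts[present] else as.numeric(sums[, 1L])
  cells$phenotype_intensity <- NA_real_
  m <- match(cells$cell_id, present)
  cells$phenotype_intensity <- value[m]
  cells
}

#' Threshold for expressing-cell classification
#'
#' Derives the intensity threshold that separates phenotype-expressing from
#' silenced cells. Strategies:
#' * `"fixed"` — `value` is used as-is;
#' * `"otsu"` — Otsu's method over the pooled per-cell intensity
#'   distribution;
#' * `"control"` — a low percentile (default 5th) of per-cell intensity
#'   among cells on negative-control spots/wells of the same batch, so the
#'   threshold excludes only the low-expressing tail and batches stay
#'   comparable.
#'
#' @param cells a `cell_records` data frame with `phenotype_intensity` set.
#' @param strategy one of `"control"`, `"otsu"`, `"fixed"`.
#' @param value fixed threshold (strategy `"fixed"`).
#' @param control_intensities per-cell intensities of control cells
#'   (strategy `"control"`).
#' @param percentile percentile of the control distribution (default 0.05).
#' @return a single numeric threshold.
#' @export
phenotype_threshold <- function(cells = NULL,
                                strategy = c("control", "otsu", "fixed"),
                                value = NULL, control_intensities = NULL,
                                percentile = 0.05) {
  strategy <- match.arg(strategy)
  switch(strategy,
    fixed = {
      if (is.null(value))
        stop_pa("fixed strategy needs a value",
                class = "phenoarray_bad_threshold")
      value
    },
    otsu = {
      if (is.null(cells) || nrow(cells) == 0L)
        stop_pa("otsu strategy needs cells with intensities",
                class = "phenoarray_bad_threshold")
      otsu_threshold(cells$phenotype_intensity)
    },
    control = {
      if (is.null(control_intensities) || length(control_intensities) == 0L)
        stop_pa("control strategy needs control-cell intensities",
                class = "phenoarray_bad_threshold")
      as.numeric(quantile(control_intensities, percentile, names = FALSE))
    })
}

#' Classify cells as expressing or silenced
#'
#' A cell is expressing when its per-cell phenotype intensity is strictly
#' above the threshold. Raising the threshold never increases the
#' expressing count.
#'
#' @param cells a `cell_records` data frame with `phenotype_intensity` set.
#' @param threshold a numeric threshold, or a strategy name passed to
#'   [phenotype_threshold()] (`"otsu"` uses the pooled intensities of
#'   `cells`).
#' @param ... passed to [phenotype_threshold()] when `threshold` is a
#'   strategy name.
#' @return `cells` with `expressing` set; the threshold used is attached as
#'   attribute `threshold`.
#' @export
classify_expressing <- function(cells, threshold, ...) {
  if (nrow(cells) == 0L) {
    attr(cells, "threshold") <- NA_real_
    return(cells)
  }
  if (anyNA(cells$phenotype_intensity))
    stop_pa("phenotype_intensity must be set before classification",
            class = "phenoarray_bad_arg")
  thr <- if (is.numeric(threshold)) threshold else
    phenotype_threshold(cells, strategy = threshold, ...)
  cells$expressing <- cells$phenotype_intensity > thr
  attr(cells, "threshold") <- thr
  cells
}

#' Attach physical coordinates to cell records
#'
#' @param cells a `cell_records` data frame.
#' @param um_per_pixel pixel scale.
#' @param field_origin `c(x, y)` micrometre offset of the field.
#' @return `cells` with `x_um` / `y_um` columns.
#' @export
add_physical_coords <- function(cells, um_per_pixel,
                                field_origin = c(0, 0)) {
  cells$x_um <- px_center_um(cells$x_px + 1, field_origin[1L],
                             um_per_pixel)
  cells$y_um <- px_center_um(cells$y_px + 1, field_origin[2L],
                             um_per_pixel)
  cells
}
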