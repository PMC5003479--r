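# Ground-truth evaluation helpers for benchmarking the pipeline against the
# synthetic scene generator.

#' Greedy one-to-one point matching within a radius
#'
#' Pairs points of set A with points of set B, nearest pair first, each
#' point used at most once, only pairs closer than `max_dist`. Candidate
#' pairs are found with a spatial grid, so large point sets stay cheap.
#'
#' @param ax,ay,bx,by point coordinates.
#' @param max_dist maximum pairing distance (same units as coordinates).
#' @return data frame with `a`, `b` (indices into the input sets) and
#'   `dist` for each matched pair.
#' @export
match_points <- function(ax, ay, bx, by, max_dist) {
  na <- length(ax); nb <- length(bx)
  if (na == 0L || nb == 0L)
    return(data.frame(a = integer(), b = integer(), dist = numeric()))
  cell <- max_dist
  key <- function(x, y) paste(floor(x / cell), floor(y / cell))
  b_bins <- split(seq_len(nb), key(bx, by))
  cand_a <- integer(); cand_b <- integer(); cand_d <- numeric()
  kbx <- floor(bx / cell); kby <- floor(by / cell)
  for (i in seq_len(na)) {
    cx <- floor(ax[i] / cell); cy <- floor(ay[i] / cell)
    for (dx in -1:1) for (dy in -1:1) {
      js <- b_bins[[paste(cx + dx, cy + dy)]]
      if (is.null(js)) next
      d <- sqrt((bx[js] - ax[i])^2 + (by[js] - ay[i])^2)
      ok <- d <= max_dist
      if (any(ok)) {
        cand_a <- c(cand_a, rep(i, sum(ok)))
        cand_b <- c(cand_b, js[ok])
        cand_d <- c(cand_d, d[ok])
      }
    }
  }
  ord <- order(cand_d)
  used_a <- logical(na); used_b <- logical(nb)
  keep <- logical(length(ord))
  for (k in ord) {
    if (!used_a[cand_a[k]] && !used_b[cand_b[k]]) {
      keep[k] <- TRUE
      used_a[cand_a[k]] <- TRUE
      used_b[cand_b[k]] <- TRUE
    }
  }
  data.frame(a = cand_a[keep], b = cand_b[keep], dist = cand_d[keep])
}

#' Score segmentation against scene ground truth
#'
#' Matches ground-truth cell centres to segmented centroids (greedy,
#' one-to-one) within `max_dist_um` and reports recall, precision and the
#' mean centroid error of matched cells.
#'
#' @param scene a `synthetic_scene`.
#' @param cells segmented `cell_records` with physical coordinates
#'   (see [add_physical_coords()]).
#' @param max_dist_um matching radius; default: the scene's mean nucleus
#'   radius.
#' @return list with `recall`, `precision`, `n_truth`, `n_detected`,
#'   `mean_centroid_error_um`.
#' @export
evaluate_segmentation <- function(scene, cells, max_dist_um = NULL) {
  gt <- scene$truth$cells
  max_dist_um <- max_dist_um %||% scene$params$nucleus_radius_mean
  m <- match_points(gt$x_um, gt$y_um, cells$x_um, cells$y_um, max_dist_um)
  list(recall = if (nrow(gt)) nrow(m) / nrow(gt) else NA_real_,
       precision = if (nrow(cells)) nrow(m) / nrow(cells) else NA_real_,
       n_truth = nrow(gt), n_detected = nrow(cells),
       mean_centroid_error_um = if (nrow(m)) mean(m$dist) else NA_real_)
}

#' Score spot detection against the layout
#'
#' Matches detections to the true spot centres within half a spot radius
#' and reports precision and recall.
#'
#' @param scene a `synthetic_scene` rendered from a layout.
#' @param detections a [detect_spots()] result.
#' @return list with `recall`, `precision`, `n_truth`, `n_detected`.
#' @export
evaluate_spot_detection <- function(scene, detections) {
  sp <- scene$truth$spots
  origin <- scene$field$field_origin
  upp <- scene$field$um_per_pixel
  dx <- px_center_um(detections$x_px + 1, origin[1L], upp)
  dy <- px_center_um(detections$y_px + 1, origin[2L], upp)
  layout <- scene$params$layout
  m <- match_points(sp$center_x, sp$center_y, dx, dy,
                    layout$spot_diameter / 4)
  list(recall = if (nrow(sp)) nrow(m) / nrow(sp) else NA_real_,
       precision = if (nrow(detections)) nrow(m) / nrow(detections)
         else NA_real_,
       n_truth = nrow(sp), n_detected = nrow(detections))
}
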