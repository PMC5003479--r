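#' Plan a printable spot grid for a slide
#'
#' Computes the densest row-major rectangular grid of circular spots that
#' fits the printable region of a slide (the slide minus a margin on each
#' side), at a centre-to-centre pitch of `spot_diameter + edge_gap` in both
#' axes. The default geometry mirrors a standard 26 x 76 mm microscope slide
#' printed with 300 micrometre spots separated by 200 micrometre gaps.
#'
#' Coordinates are physical micrometres with the origin at the top-left
#' corner of the printable region, x along the slide's long axis and y along
#' the short axis. Spot ids are integers in row-major order.
#'
#' @param slide_width,slide_height slide dimensions in micrometres.
#' @param spot_diameter printed spot diameter in micrometres.
#' @param edge_gap empty space between adjacent spot edges, micrometres
#'   (>= 0).
#' @param margin unprintable border on each side, micrometres (>= 0).
#' @return a `grid_layout` object: a list with the geometry fields, `n_rows`,
#'   `n_cols`, and a `spots` data frame (`spot_id`, `row`, `col`,
#'   `center_x`, `center_y`, `reagent_label`, `role`).
#' @examples
#' layout <- plan_grid()
#' layout$n_rows * layout$n_cols   # 6336 spots on one slide
#' @export
plan_grid <- function(slide_width = 76000, slide_height = 26000,
                      spot_diameter = 300, edge_gap = 200, margin = 2000) {
  if (slide_width <= 0 || slide_height <= 0 || spot_diameter <= 0)
    stop_pa("slide dimensions and spot diameter must be positive",
            class = "phenoarray_bad_arg")
  if (edge_gap < 0 || margin < 0)
    stop_pa("edge_gap and margin must be non-negative",
            class = "phenoarray_bad_arg")
  pitch <- spot_diameter + edge_gap
  usable_x <- slide_width - 2 * margin
  usable_y <- slide_height - 2 * margin
  if (usable_x < spot_diameter || usable_y < spot_diameter)
    stop_pa(paste0("zero-capacity layout: printable region ",
                   "%g x %g um cannot hold a %g um spot"),
            usable_x, usable_y, spot_diameter,
            class = "phenoarray_zero_capacity")
  n_cols <- floor((usable_x - spot_diameter) / pitch) + 1
  n_rows <- floor((usable_y - spot_diameter) / pitch) + 1
  rows <- rep(seq_len(n_rows), each = n_cols)
  cols <- rep(seq_len(n_cols), times = n_rows)
  spots <- data.frame(
    spot_id = seq_len(n_rows * n_cols),
    row = rows, col = cols,
    center_x = spot_diameter / 2 + (cols - 1) * pitch,
    center_y = spot_diameter / 2 + (rows - 1) * pitch,
    reagent_label = NA_character_,
    role = "test",
    stringsAsFactors = FALSE)
  structure(list(slide_width = slide_width, slide_height = slide_height,
                 spot_diameter = spot_diameter, edge_gap = edge_gap,
                 margin = margin, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), spots = spots),
            class = "grid_layout")
}

#' @export
print.grid_layout <- function(x, ...) {
  cat(sprintf(
    "grid_layout: %d x %d spots (%d total), %g um spots at %g um pitch\n",
    x$n_rows, x$n_cols, nrow(x$spots), x$spot_diameter,
    x$spot_diameter + x$edge_gap))
  cat(sprintf("  slide %g x %g um, margin %g um per side\n",
              x$slide_width, x$slide_height, x$margin))
  roles <- table(x$spots$role)
  cat("  roles:", paste(names(roles), roles, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Centre-to-centre pitch of a layout
#' @param layout a `grid_layout`.
#' @return pitch in micrometres.
#' @export
grid_pitch <- function(layout) layout$spot_diameter + layout$edge_gap

#' Extract a rectangular sub-grid of a layout
#'
#' Convenience for simulating one imaged field: keeps spots in the given row
#' and column ranges (ids and coordinates unchanged).
#'
#' @param layout a `grid_layout`.
#' @param rows,cols integer vectors of row / column indices to keep.
#' @return a `grid_layout` restricted to those spots.
#' @export
subset_grid <- function(layout, rows, cols) {
  keep <- layout$spots$row %in% rows & layout$spots$col %in% cols
  layout$spots <- layout$spots[keep, , drop = FALSE]
  layout
}

#' Randomly allocate negative-control spots
#'
#' Assigns exactly `round_half_up(spots_per_array * control_fraction)` spots
#' the `negative_control` role, scattered uniformly at random (reproducibly,
#' from `seed`); all other spots keep the `test` role.
#'
#' @param spots_per_array number of spots on the array.
#' @param control_fraction fraction of spots used as negative controls, in
#'   \[0, 1\] (16% in the printed genome library).
#' @param seed integer seed for the scatter.
#' @return character vector of roles, indexed by spot id.
#' @examples
#' table(allocate_controls(3888, 0.16, seed = 1))  # 622 controls
#' @export
allocate_controls <- function(spots_per_array, control_fraction, seed) {
  if (control_fraction < 0 || control_fraction > 1)
    stop_pa("control_fraction must be in [0, 1]",
            class = "phenoarray_bad_arg")
  n_controls <- round_half_up(spots_per_array * control_fraction)
  roles <- rep("test", spots_per_array)
  if (n_controls > 0) {
    ids <- withr::with_seed(seed,
      sample.int(spots_per_array, n_controls))
    roles[ids] <- "negative_control"
  }
  roles
}

#' Apply roles and reagent labels to a layout
#'
#' @param layout a `grid_layout`.
#' @param roles character vector of roles (`test`, `negative_control`,
#'   `blank`), length = number of spots.
#' @param labels optional reagent labels for test spots; controls receive
#'   `control_label`.
#' @param control_label reagent label given to negative-control spots.
#' @return the layout with `spots$role` / `spots$reagent_label` filled in.
#' @export
set_spot_roles <- function(layout, roles, labels = NULL,
                           control_label = "NTC") {
  n <- nrow(layout$spots)
  stopifnot(length(roles) == n)
  bad <- setdiff(unique(roles), c("test", "negative_control", "blank"))
  if (length(bad))
    stop_pa("unknown spot role(s): %s", paste(bad, collapse = ", "),
            class = "phenoarray_bad_arg")
  layout$spots$role <- roles
  layout$spots$reagent_label <- NA_character_
  layout$spots$reagent_label[roles == "negative_control"] <- control_label
  test_idx <- which(roles == "test")
  if (!is.null(labels)) {
    if (length(labels) > length(test_idx))
      stop_pa("more labels (%d) than test spots (%d)", length(labels),
              length(test_idx), class = "phenoarray_capacity_exceeded")
    layout$spots$reagent_label[test_idx[seq_along(labels)]] <- labels
    extra <- test_idx[seq_along(test_idx) > length(labels)]
    layout$spots$role[extra] <- "blank"
  } else {
    layout$spots$reagent_label[test_idx] <-
      sprintf("test_%04d", seq_along(test_idx))
  }
  layout
}

#' Partition a reagent library across a multi-array set
#'
#' Fills arrays in order with the given reagent labels; each array carries
#' `round_half_up(spots_per_array * control_fraction)` negative-control
#' spots (scattered reproducibly), and test positions left over after the
#' library is exhausted become blanks. A genome-scale example: 16,330 labels
#' fill a 5-array set of 3,888 spots per array at 16% controls exactly.
#'
#' @param reagent_labels character vector of unique test reagent labels.
#' @param n_arrays number of arrays in the set.
#' @param spots_per_array spots printed per array.
#' @param control_fraction fraction of negative-control spots per array.
#' @param seed integer seed for control placement (one sub-seed per array).
#' @param control_label label used for every control spot.
#' @return a `library_plan`: list with `n_arrays`, `spots_per_array`,
#'   `control_fraction`, `controls_per_array` and `assignments`, a list of
#'   per-array data frames (`position`, `role`, `reagent_label`).
#' @export
partition_library <- function(reagent_labels, n_arrays, spots_per_array,
                              control_fraction, seed = 1L,
                              control_label = "NTC") {
  if (anyDuplicated(reagent_labels))
    stop_pa("reagent labels must be unique", class = "phenoarray_bad_arg")
  controls_per_array <-
    round_half_up(spots_per_array * control_fraction)
  test_per_array <- spots_per_array - controls_per_array
  capacity <- n_arrays * test_per_array
  n_labels <- length(reagent_labels)
  if (n_labels > capacity)
    stop_pa(paste0("library capacity exceeded: %d labels for %d test ",
                   "positions (%d arrays x %d), short by %d"),
            n_labels, capacity, n_arrays, test_per_array,
            n_labels - capacity,
            class = "phenoarray_capacity_exceeded")
  assignments <- vector("list", n_arrays)
  cursor <- 0L
  for (a in seq_len(n_arrays)) {
    roles <- allocate_controls(spots_per_array, control_fraction,
                               seed = seed + a - 1L)
    labels <- rep(NA_character_, spots_per_array)
    labels[roles == "negative_control"] <- control_label
    test_pos <- which(roles == "test")
    take <- min(length(test_pos), n_labels - cursor)
    if (take > 0)
      labels[test_pos[seq_len(take)]] <-
        reagent_labels[cursor + seq_len(take)]
    if (take < length(test_pos))
      roles[test_pos[seq_along(test_pos) > take]] <- "blank"
    cursor <- cursor + take
    assignments[[a]] <- data.frame(position = seq_len(spots_per_array),
                                   role = roles, reagent_label = labels,
                                   stringsAsFactors = FALSE)
  }
  structure(list(n_arrays = n_arrays, spots_per_array = spots_per_array,
                 control_fraction = control_fraction,
                 controls_per_array = controls_per_array,
                 assignments = assignments),
            class = "library_plan")
}

#' @export
print.library_plan <- function(x, ...) {
  n_test <- sum(vapply(x$assignments,
                       function(a) sum(a$role == "test"), 0L))
  n_blank <- sum(vapply(x$assignments,
                        function(a) sum(a$role == "blank"), 0L))
  cat(sprintf(
    "library_plan: %d arrays x %d spots (%d controls/array)\n",
    x$n_arrays, x$spots_per_array, x$controls_per_array))
  cat(sprintf("  %d test spots used, %d blank\n", n_test, n_blank))
  invisible(x)
}
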