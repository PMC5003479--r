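#' Assign cells to spots by nominal disc containment
#'
#' A cell is assigned to spot *s* when its nucleus centroid lies within
#' `association_radius_factor * spot_diameter / 2` of the (registered) spot
#' centre; a cell in range of several spots goes to the nearest centre,
#' exact ties to the lower spot id; cells in range of none stay unassigned.
#'
#' @param cells a `cell_records` data frame carrying `x_um` / `y_um`
#'   (see [add_physical_coords()]).
#' @param spots data frame with `spot_id`, `center_x`, `center_y` and
#'   either a `diameter` column or the common `spot_diameter` argument.
#' @param spot_diameter nominal spot diameter in micrometres, used when
#'   `spots` has no `diameter` column.
#' @param association_radius_factor multiplier on the nominal spot radius
#'   (default 1).
#' @return `cells` with `assigned_spot_id` filled in.
#' @export
assign_cells_to_spots <- function(cells, spots, spot_diameter = NULL,
                                  association_radius_factor = 1.0) {
  if (!all(c("x_um", "y_um") %in% names(cells)))
    stop_pa("cells need x_um/y_um; run add_physical_coords() first",
            class = "phenoarray_bad_arg")
  diam <- if ("diameter" %in% names(spots)) spots$diameter else {
    if (is.null(spot_diameter))
      stop_pa("spot diameter not given", class = "phenoarray_bad_arg")
    rep(spot_diameter, nrow(spots))
  }
  if (nrow(cells) == 0L || nrow(spots) == 0L) return(cells)
  cells$assigned_spot_id <- NA_integer_
  # order spots by id so that which.min's first-minimum rule breaks exact
  # distance ties toward the lower spot id
  ord <- order(spots$spot_id)
  spots <- spots[ord, , drop = FALSE]
  diam <- diam[ord]
  max_r <- association_radius_factor * diam / 2
  d2 <- outer(cells$x_um, spots$center_x, "-")^2 +
    outer(cells$y_um, spots$center_y, "-")^2
  within <- sweep(sqrt(d2), 2L, max_r, "<=")
  for (i in seq_len(nrow(cells))) {
    ok <- which(within[i, ])
    if (length(ok))
      cells$assigned_spot_id[i] <- spots$spot_id[ok[which.min(d2[i, ok])]]
  }
  cells
}

#' Percent of expressing cells in a group
#'
#' Counts expressing cells and reports `100 * n_expressing / n_cells`.
#' Groups below `min_cells` are flagged low-count (reported, not dropped).
#'
#' @param cells `cell_records` with `expressing` set (one group, e.g. the
#'   cells of one spot or well).
#' @param spot_id,reagent_label,role metadata copied into the result.
#' @param min_cells minimum cell count for an unflagged result.
#' @return one-row data frame (`spot_result`): `spot_id`, `reagent_label`,
#'   `role`, `n_cells`, `n_expressing`, `percent_expressing`, `low_count`.
#' @export
percent_expressing <- function(cells, spot_id = NA_integer_,
                               reagent_label = NA_character_,
                               role = NA_character_, min_cells = 20L) {
  n <- nrow(cells)
  if (n == 0L)
    stop_pa("percent expressing undefined for an empty group (spot %s)",
            as.character(spot_id), class = "phenoarray_undefined_percent")
  if (anyNA(cells$expressing))
    stop_pa("expressing flags must be set",
            class = "phenoarray_bad_arg")
  n_exp <- sum(cells$expressing)
  data.frame(spot_id = spot_id, reagent_label = reagent_label, role = role,
             n_cells = n, n_expressing = n_exp,
             percent_expressing = 100 * n_exp / n,
             low_count = n < min_cells, stringsAsFactors = FALSE)
}

#' Normalize per-replicate percentages to the negative control
#'
#' Each replicate value becomes `100 * raw / mean(raw of control)`, so the
#' control condition's mean normalized expression is exactly 100 and
#' knockdown is `100 - mean`. Conditions are compared to the control with a
#' two-sample Student's t-test (see [knockdown_test()]).
#'
#' @param results data frame with columns `condition` and
#'   `percent_expressing` (one row per replicate spot or well).
#' @param control_condition name of the negative-control condition.
#' @return data frame of `normalized_condition`s: `condition`, `n`,
#'   `mean_normalized_expression`, `sd`, `knockdown_percent`,
#'   `t_statistic`, `p_value` (`NA` for the control itself and for
#'   conditions with fewer than 2 replicates), plus a `replicates`
#'   list-column of the normalized values.
#' @export
normalize_to_control <- function(results, control_condition) {
  if (!control_condition %in% results$condition)
    stop_pa("control condition '%s' absent", control_condition,
            class = "phenoarray_bad_arg")
  ctrl_raw <- results$percent_expressing[
    results$condition == control_condition]
  ctrl_mean <- mean(ctrl_raw)
  if (ctrl_mean == 0)
    stop_pa("normalization undefined: control mean is zero",
            class = "phenoarray_normalization_undefined")
  results$normalized <- 100 * results$percent_expressing / ctrl_mean
  ctrl_norm <- results$normalized[results$condition == control_condition]
  conds <- unique(results$condition)
  out <- lapply(conds, function(cond) {
    vals <- results$normalized[results$condition == cond]
    tt <- if (cond != control_condition && length(vals) >= 2L &&
              length(ctrl_norm) >= 2L)
      knockdown_test(vals, ctrl_norm) else
      list(t_statistic = NA_real_, p_value = NA_real_)
    data.frame(condition = cond, n = length(vals),
               mean_normalized_expression = mean(vals),
               sd = if (length(vals) > 1L) sd(vals) else 0,
               knockdown_percent = 100 - mean(vals),
               t_statistic = tt$t_statistic, p_value = tt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$replicates <- lapply(conds, function(cond)
    results$normalized[results$condition == cond])
  class(out) <- c("normalized_conditions", "data.frame")
  out
}

#' Two-sample Student's t-test for knockdown significance
#'
#' Equal-variance, two-sided t-test on normalized replicate values, as used
#' to compare each reagent condition against the negative control. A
#' warning is emitted when the group variances differ by more than 4-fold
#' (the equal-variance assumption is then questionable).
#'
#' @param test_values,control_values numeric vectors (each length >= 2).
#' @return list with `t_statistic`, `df` and `p_value`.
#' @export
knockdown_test <- function(test_values, control_values) {
  n1 <- length(test_values); n2 <- length(control_values)
  if (n1 < 2L || n2 < 2L)
    stop_pa("each group needs at least 2 values",
            class = "phenoarray_bad_arg")
  v1 <- stats::var(test_values); v2 <- stats::var(control_values)
  if (v1 > 0 && v2 > 0 && (max(v1, v2) / min(v1, v2)) > 4)
    warning("group variances differ by more than 4-fold; ",
            "equal-variance t-test may be unreliable")
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t_stat <- if (se == 0) 0 else
    (mean(test_values) - mean(control_values)) / se
  p <- if (se == 0 && mean(test_values) == mean(control_values)) 1 else
    2 * stats::pt(-abs(t_stat), df)
  list(t_statistic = t_stat, df = df, p_value = p)
}

#' Default end-to-end pipeline configuration
#'
#' @param ... overrides for individual entries.
#' @return named list of pipeline parameters: spot detection
#'   (`spot_threshold`, `min_spot_diameter`, `max_spot_diameter`,
#'   `max_displacement`), segmentation (`nucleus_threshold`,
#'   `min_nucleus_area`, `max_nucleus_area`, `smooth_sigma_um`,
#'   `marker_min_dist_um`), measurement (`dilation_radius_um`,
#'   `intensity_statistic`), classification (`threshold_strategy`,
#'   `threshold_value`, `control_percentile`), association
#'   (`association_radius_factor`) and reporting (`min_cells`).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    spot_threshold = "otsu", min_spot_diameter = 150,
    max_spot_diameter = 600, max_displacement = 100,
    nucleus_threshold = "otsu", min_nucleus_area = 30,
    max_nucleus_area = 500, smooth_sigma_um = 1.0,
    marker_min_dist_um = 4,
    dilation_radius_um = 3, intensity_statistic = "mean",
    threshold_strategy = "control", threshold_value = NULL,
    control_percentile = 0.05,
    association_radius_factor = 1.0, min_cells = 20L)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop_pa("unknown config entries: %s", paste(unknown, collapse = ", "),
            class = "phenoarray_bad_arg")
  modifyList(cfg, overrides)
}

#' Quantify one array field end to end
#'
#' Runs the full chain: detect spots in the tracer channel, register them to
#' the layout, segment nuclei, measure per-cell phenotype intensity,
#' classify expressing cells (by default against a control-derived
#' threshold), assign cells to registered spot discs, score per-spot percent
#' expressing, normalize to the negative-control condition and test each
#' condition's knockdown. Conditions are reagent labels; replicate unit =
#' one spot.
#'
#' @param field a [multi_channel_field()].
#' @param layout a [plan_grid()] layout with roles set
#'   (see [set_spot_roles()]); the negative-control spots define the 100%
#'   baseline.
#' @param config a [pipeline_config()].
#' @param control_condition reagent label of the negative control; default:
#'   the label of the layout's `negative_control` spots.
#' @return an `array_quantification`: list with `detections`, `cells`,
#'   `spot_results`, `conditions`, `threshold` and `translation_um`.
#' @export
quantify_array <- function(field, layout, config = pipeline_config(),
                           control_condition = NULL) {
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop_pa("stage '%s' failed: %s", name, conditionMessage(e),
                class = "phenoarray_stage_error")),
      message = function(m) invokeRestart("muffleMessage"))
    message(sprintf("[quantify_array] %-14s %6.2f s", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  upp <- field$um_per_pixel
  detections <- stage("detect_spots", detect_spots(
    field$tracer, upp, config$min_spot_diameter,
    config$max_spot_diameter, config$spot_threshold))
  detections <- stage("register", register_to_layout(
    detections, layout, field$field_origin, upp,
    config$max_displacement))
  seg <- stage("segment", segment_nuclei(
    field$nuclei, upp, config$min_nucleus_area, config$max_nucleus_area,
    config$smooth_sigma_um, config$marker_min_dist_um,
    config$nucleus_threshold))
  cells <- stage("measure", measure_phenotype(
    seg$cells, seg$labels, field$phenotype, upp,
    config$dilation_radius_um, config$intensity_statistic))
  cells <- add_physical_coords(cells, upp, field$field_origin)

  # registered spot centres: expected centre + estimated translation;
  # only spots near the imaged field are candidates for association
  translation <- attr(detections, "translation_um") %||% c(0, 0)
  sp <- layout$spots
  fw <- ncol(field$tracer) * upp
  fh <- nrow(field$tracer) * upp
  near <- sp$center_x > field$field_origin[1L] - layout$spot_diameter &
    sp$center_x < field$field_origin[1L] + fw + layout$spot_diameter &
    sp$center_y > field$field_origin[2L] - layout$spot_diameter &
    sp$center_y < field$field_origin[2L] + fh + layout$spot_diameter
  sp <- sp[near, , drop = FALSE]
  reg_spots <- data.frame(spot_id = sp$spot_id,
                          center_x = sp$center_x + translation[1L],
                          center_y = sp$center_y + translation[2L],
                          diameter = layout$spot_diameter,
                          reagent_label = sp$reagent_label,
                          role = sp$role, stringsAsFactors = FALSE)
  cells <- stage("assign", assign_cells_to_spots(
    cells, reg_spots,
    association_radius_factor = config$association_radius_factor))

  control_condition <- control_condition %||% {
    lab <- unique(sp$reagent_label[sp$role == "negative_control"])
    if (length(lab) != 1L)
      stop_pa("cannot infer control condition; pass control_condition",
              class = "phenoarray_bad_arg")
    lab
  }
  ctrl_spots <- sp$spot_id[sp$reagent_label == control_condition]
  ctrl_int <- cells$phenotype_intensity[
    cells$assigned_spot_id %in% ctrl_spots]
  thr <- switch(config$threshold_strategy,
    control = phenotype_threshold(
      control_intensities = ctrl_int, strategy = "control",
      percentile = config$control_percentile),
    otsu = phenotype_threshold(cells, strategy = "otsu"),
    fixed = phenotype_threshold(strategy = "fixed",
                                value = config$threshold_value),
    stop_pa("unknown threshold strategy '%s'", config$threshold_strategy,
            class = "phenoarray_bad_threshold"))
  cells <- classify_expressing(cells, thr)

  # per-spot scoring over spots that actually received cells
  assigned <- cells[!is.na(cells$assigned_spot_id), , drop = FALSE]
  spot_ids <- sort(unique(assigned$assigned_spot_id))
  spot_results <- do.call(rbind, lapply(spot_ids, function(s) {
    meta <- sp[sp$spot_id == s, ]
    percent_expressing(assigned[assigned$assigned_spot_id == s, ],
                       spot_id = s, reagent_label = meta$reagent_label,
                       role = meta$role, min_cells = config$min_cells)
  }))
  if (is.null(spot_results) || nrow(spot_results) == 0L)
    stop_pa("no spot received any cells", class = "phenoarray_stage_error")
  scored <- data.frame(condition = spot_results$reagent_label,
                       percent_expressing =
                         spot_results$percent_expressing,
                       stringsAsFactors = FALSE)
  conditions <- normalize_to_control(scored, control_condition)

  structure(list(detections = detections, cells = cells,
                 spot_results = spot_results, conditions = conditions,
                 threshold = thr, translation_um = translation,
                 control_condition = control_condition),
            class = "array_quantification")
}

#' @export
print.array_quantification <- function(x, ...) {
  cat(sprintf(
    "array_quantification: %d spots detected, %d cells, threshold %.1f\n",
    nrow(x$detections), nrow(x$cells), x$threshold))
  df <- x$conditions
  df$replicates <- NULL
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}
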