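#' Parameters of a synthetic microscopy scene
#'
#' Describes a simulated three-channel fluorescence field of a cell
#' monolayer, optionally seeded over a printed spot array. Defaults mirror
#' the imaging conditions of the assay the package targets: 300 micrometre
#' spots at 500 micrometre pitch, a 10x-objective pixel scale of 1.33
#' micrometres per pixel, a subconfluent monolayer of 1,500 cells per square
#' millimetre, and a per-cell phenotype intensity that is bimodal between
#' "expressing" and "silenced" cells (18 intensity standard deviations
#' apart, so classification errors are dominated by segmentation, not by
#' overlap of the two intensity modes).
#'
#' @param layout a [plan_grid()] layout (or `NULL` for well mode).
#' @param um_per_pixel pixel scale, micrometres per pixel.
#' @param cell_density expected cells per square millimetre; the realized
#'   count is Poisson.
#' @param nucleus_radius_mean,nucleus_radius_sd nucleus radius distribution,
#'   micrometres.
#' @param expressing_intensity_mean,silenced_intensity_mean mean per-cell
#'   phenotype intensity (arbitrary units) for expressing / silenced cells;
#'   the former must exceed the latter.
#' @param intensity_sd standard deviation of the per-cell intensity draw.
#' @param per_spot_silenced_fraction named numeric vector mapping spot id to
#'   the probability that a cell over that spot is silenced; spots not named
#'   fall back to `default_spot_silenced_fraction`.
#' @param default_spot_silenced_fraction silenced probability for spots not
#'   listed explicitly.
#' @param off_spot_silenced_fraction silenced probability for cells between
#'   spots (and for every cell in well mode).
#' @param tracer_spot_intensity peak tracer intensity painted on each spot.
#' @param nucleus_intensity peak nuclear-stain intensity per nucleus.
#' @param background_level,background_noise_sd additive background and its
#'   Gaussian read-noise standard deviation (all channels).
#' @param phenotype_halo_um the phenotype stain extends this far beyond the
#'   nucleus edge (whole-cell stain approximated by a perinuclear halo).
#' @param nucleus_exclusion_factor cell centres are placed by sequential
#'   random inhibition: a candidate is rejected while it lies closer than
#'   `nucleus_exclusion_factor * (r_i + r_j)` to an already placed nucleus
#'   (nuclei are solid bodies: they may touch and partially overlap, but
#'   not coincide). When a position cannot be found after repeated
#'   attempts — crowded fields — the constraint is dropped for that cell,
#'   so overlapping nuclei still occur at high density. Set to 0 for pure
#'   Poisson placement.
#' @param field_origin numeric `c(x, y)` micrometre offset of the field's
#'   top-left corner into the slide; default: the layout's spot bounding box
#'   minus half a pitch (well mode: `c(0, 0)`).
#' @param field_width_um,field_height_um field size in micrometres; default:
#'   the layout bounding box plus one pitch (well mode: 2,000 each).
#' @param seed integer seed; every random draw derives from it.
#' @return a `scene_params` object (validated list).
#' @export
scene_params <- function(layout = NULL,
                         um_per_pixel = 1.33,
                         cell_density = 1500,
                         nucleus_radius_mean = 7,
                         nucleus_radius_sd = 1,
                         expressing_intensity_mean = 1000,
                         silenced_intensity_mean = 100,
                         intensity_sd = 50,
                         per_spot_silenced_fraction = NULL,
                         default_spot_silenced_fraction = 0,
                         off_spot_silenced_fraction = 0,
                         tracer_spot_intensity = 8000,
                         nucleus_intensity = 3000,
                         background_level = 100,
                         background_noise_sd = 10,
                         phenotype_halo_um = 3,
                         nucleus_exclusion_factor = 0.8,
                         field_origin = NULL,
                         field_width_um = NULL,
                         field_height_um = NULL,
                         seed = 1L) {
  if (um_per_pixel <= 0)
    stop_pa("um_per_pixel must be positive", class = "phenoarray_bad_arg")
  fracs <- c(per_spot_silenced_fraction, default_spot_silenced_fraction,
             off_spot_silenced_fraction)
  if (any(fracs < 0 | fracs > 1))
    stop_pa("silenced fractions must be in [0, 1]",
            class = "phenoarray_bad_arg")
  if (expressing_intensity_mean <= silenced_intensity_mean)
    stop_pa("expressing intensity mean must exceed silenced mean",
            class = "phenoarray_bad_arg")
  if (cell_density < 0)
    stop_pa("cell_density must be non-negative",
            class = "phenoarray_bad_arg")
  structure(list(
    layout = layout, um_per_pixel = um_per_pixel,
    cell_density = cell_density,
    nucleus_radius_mean = nucleus_radius_mean,
    nucleus_radius_sd = nucleus_radius_sd,
    expressing_intensity_mean = expressing_intensity_mean,
    silenced_intensity_mean = silenced_intensity_mean,
    intensity_sd = intensity_sd,
    per_spot_silenced_fraction = per_spot_silenced_fraction,
    default_spot_silenced_fraction = default_spot_silenced_fraction,
    off_spot_silenced_fraction = off_spot_silenced_fraction,
    tracer_spot_intensity = tracer_spot_intensity,
    nucleus_intensity = nucleus_intensity,
    background_level = background_level,
    background_noise_sd = background_noise_sd,
    phenotype_halo_um = phenotype_halo_um,
    nucleus_exclusion_factor = nucleus_exclusion_factor,
    field_origin = field_origin,
    field_width_um = field_width_um,
    field_height_um = field_height_um,
    seed = as.integer(seed)), class = "scene_params")
}

#' A multi-channel imaged field
#'
#' Three co-registered 2-D intensity grids (tracer ~560 nm, phenotype
#' ~488 nm, nuclei ~635 nm) sharing shape and pixel scale.
#'
#' @param tracer,phenotype,nuclei numeric matrices of identical shape with
#'   non-negative intensities.
#' @param um_per_pixel micrometres per pixel.
#' @param field_origin `c(x, y)` micrometre offset of pixel (1, 1)'s corner
#'   into the slide frame.
#' @return a `multi_channel_field` object.
#' @export
multi_channel_field <- function(tracer, phenotype, nuclei, um_per_pixel,
                                field_origin = c(0, 0)) {
  dims <- list(dim(tracer), dim(phenotype), dim(nuclei))
  if (!all(vapply(dims, identical, TRUE, dims[[1L]])))
    stop_pa("channel shapes differ", class = "phenoarray_shape_mismatch")
  if (min(tracer, phenotype, nuclei) < 0)
    stop_pa("intensities must be non-negative",
            class = "phenoarray_bad_arg")
  structure(list(tracer = tracer, phenotype = phenotype, nuclei = nuclei,
                 um_per_pixel = um_per_pixel,
                 field_origin = as.numeric(field_origin)),
            class = "multi_channel_field")
}

#' @export
print.multi_channel_field <- function(x, ...) {
  cat(sprintf(
    "multi_channel_field: %d x %d px at %g um/px, origin (%g, %g) um\n",
    nrow(x$tracer), ncol(x$tracer), x$um_per_pixel,
    x$field_origin[1L], x$field_origin[2L]))
  invisible(x)
}

# pixel-centre <-> physical micrometre conversion (1-based pixel indices)
px_center_um <- function(px, origin, um_per_pixel) {
  origin + (px - 0.5) * um_per_pixel
}
um_to_px <- function(um, origin, um_per_pixel) {
  (um - origin) / um_per_pixel + 0.5
}

# Sequential-random-inhibition placement of n cell centres in a
# width x height micrometre rectangle. A candidate position for cell i is
# rejected while some placed cell j has distance < factor * (r[i] + r[j]);
# after max_attempts rejections the constraint is dropped for that cell
# (dense fields keep their nominal density and may overlap). Grid-binned
# neighbour lookup keeps this linear in n. factor = 0 is pure Poisson.
place_cells <- function(n, width, height, radii, factor = 0.8,
                        max_attempts = 30L) {
  x <- numeric(n); y <- numeric(n)
  if (n == 0L) return(list(x = x, y = y))
  if (factor <= 0) {
    return(list(x = runif(n) * width, y = runif(n) * height))
  }
  cell <- factor * 2 * max(radii)          # bin size >= max exclusion
  nbx <- max(1L, ceiling(width / cell))
  nby <- max(1L, ceiling(height / cell))
  bins <- vector("list", nbx * nby)
  bin_of <- function(px, py) {
    bx <- min(nbx - 1L, max(0L, floor(px / cell)))
    by <- min(nby - 1L, max(0L, floor(py / cell)))
    bx + by * nbx + 1L
  }
  for (i in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      px <- runif(1L) * width; py <- runif(1L) * height
      bx <- floor(px / cell); by <- floor(py / cell)
      ok <- TRUE
      for (dx in -1:1) for (dy in -1:1) {
        cbx <- bx + dx; cby <- by + dy
        if (cbx < 0 || cbx >= nbx || cby < 0 || cby >= nby) next
        js <- bins[[cbx + cby * nbx + 1L]]
        if (is.null(js)) next
        mind <- factor * (radii[i] + radii[js])
        if (any((x[js] - px)^2 + (y[js] - py)^2 < mind^2)) {
          ok <- FALSE
          break
        }
      }
      if (ok) { placed <- TRUE; break }
    }
    if (!placed) { px <- runif(1L) * width; py <- runif(1L) * height }
    x[i] <- px; y[i] <- py
    b <- bin_of(px, py)
    bins[[b]] <- c(bins[[b]], i)
  }
  list(x = x, y = y)
}

# shared renderer for field (layout) and well (no layout) modes
render_scene <- function(params, use_layout) {
  p <- params
  layout <- if (use_layout) p$layout else NULL
  if (use_layout && is.null(layout))
    stop_pa("render_field needs a layout; use render_well otherwise",
            class = "phenoarray_bad_arg")
  if (use_layout) {
    pitch <- grid_pitch(layout)
    sp <- layout$spots
    origin <- p$field_origin %||%
      c(min(sp$center_x) - pitch / 2, min(sp$center_y) - pitch / 2)
    width <- p$field_width_um %||% (diff(range(sp$center_x)) + pitch)
    height <- p$field_height_um %||% (diff(range(sp$center_y)) + pitch)
    in_field <- sp$center_x + layout$spot_diameter / 2 > origin[1L] &
      sp$center_x - layout$spot_diameter / 2 < origin[1L] + width &
      sp$center_y + layout$spot_diameter / 2 > origin[2L] &
      sp$center_y - layout$spot_diameter / 2 < origin[2L] + height
    if (!any(in_field))
      stop_pa("field does not intersect any layout spot",
              class = "phenoarray_no_overlap")
    sp <- sp[in_field, , drop = FALSE]
  } else {
    origin <- p$field_origin %||% c(0, 0)
    width <- p$field_width_um %||% 2000
    height <- p$field_height_um %||% 2000
    sp <- NULL
  }
  nc <- max(1L, as.integer(round(width / p$um_per_pixel)))
  nr <- max(1L, as.integer(round(height / p$um_per_pixel)))
  area_mm2 <- (nc * p$um_per_pixel) * (nr * p$um_per_pixel) / 1e6

  withr::with_seed(p$seed, {
    n_cells <- rpois(1L, p$cell_density * area_mm2)
    radius <- pmax(2, rnorm(n_cells, p$nucleus_radius_mean,
                            p$nucleus_radius_sd))
    pos <- place_cells(n_cells, nc * p$um_per_pixel,
                       nr * p$um_per_pixel, radius,
                       p$nucleus_exclusion_factor)
    x_um <- origin[1L] + pos$x
    y_um <- origin[2L] + pos$y
    # spot membership: centre within the nominal spot radius
    spot_id <- rep(NA_integer_, n_cells)
    if (!is.null(sp) && n_cells > 0) {
      r_spot <- layout$spot_diameter / 2
      for (i in seq_len(nrow(sp))) {
        d2 <- (x_um - sp$center_x[i])^2 + (y_um - sp$center_y[i])^2
        hit <- d2 <= r_spot^2 & is.na(spot_id)
        spot_id[hit] <- sp$spot_id[i]
      }
    }
    sil_frac <- rep(p$off_spot_silenced_fraction, n_cells)
    if (!is.null(sp) && n_cells > 0) {
      for (i in seq_len(nrow(sp))) {
        f <- p$default_spot_silenced_fraction
        key <- as.character(sp$spot_id[i])
        if (!is.null(p$per_spot_silenced_fraction) &&
            key %in% names(p$per_spot_silenced_fraction))
          f <- p$per_spot_silenced_fraction[[key]]
        sil_frac[which(spot_id == sp$spot_id[i])] <- f
      }
    }
    silenced <- runif(n_cells) < sil_frac
    cell_mean <- ifelse(silenced, p$silenced_intensity_mean,
                        p$expressing_intensity_mean)
    cell_intensity <- pmax(0, rnorm(n_cells, cell_mean, p$intensity_sd))

    zero <- matrix(0, nr, nc)
    cx <- um_to_px(x_um, origin[1L], p$um_per_pixel)
    cy <- um_to_px(y_um, origin[2L], p$um_per_pixel)
    tracer <- zero
    if (!is.null(sp)) {
      tracer <- .paint_discs(
        zero,
        um_to_px(sp$center_x, origin[1L], p$um_per_pixel),
        um_to_px(sp$center_y, origin[2L], p$um_per_pixel),
        rep(layout$spot_diameter / 2 / p$um_per_pixel, nrow(sp)),
        rep(p$tracer_spot_intensity, nrow(sp)))
    }
    nuclei <- .paint_discs(zero, cx, cy, radius / p$um_per_pixel,
                           rep(p$nucleus_intensity, n_cells))
    phenotype <- .paint_discs(
      zero, cx, cy, (radius + p$phenotype_halo_um) / p$um_per_pixel,
      cell_intensity)

    finish <- function(signal) {
      n <- length(signal)
      out <- rpois(n, signal) + p$background_level +
        rnorm(n, 0, p$background_noise_sd)
      m <- matrix(pmin(65535, pmax(0, round(out))), nr, nc)
      m
    }
    field <- multi_channel_field(finish(tracer), finish(phenotype),
                                 finish(nuclei), p$um_per_pixel, origin)
    cells <- data.frame(
      cell_id = seq_len(n_cells),
      x_um = x_um, y_um = y_um, radius_um = radius,
      expressing = !silenced, spot_id = spot_id,
      drawn_intensity = cell_intensity,
      stringsAsFactors = FALSE)
    spot_truth <- NULL
    if (!is.null(sp)) {
      requested <- vapply(as.character(sp$spot_id), function(key) {
        if (!is.null(p$per_spot_silenced_fraction) &&
            key %in% names(p$per_spot_silenced_fraction))
          p$per_spot_silenced_fraction[[key]]
        else p$default_spot_silenced_fraction
      }, 0)
      n_on <- vapply(sp$spot_id, function(s)
        sum(!is.na(spot_id) & spot_id == s), 0L)
      n_sil <- vapply(sp$spot_id, function(s)
        sum(!is.na(spot_id) & spot_id == s & silenced), 0L)
      spot_truth <- data.frame(
        spot_id = sp$spot_id, role = sp$role,
        reagent_label = sp$reagent_label,
        center_x = sp$center_x, center_y = sp$center_y,
        requested_silenced_fraction = requested,
        n_cells = n_on, n_silenced = n_sil,
        stringsAsFactors = FALSE)
    }
    structure(list(field = field,
                   truth = list(cells = cells, spots = spot_truth),
                   params = p),
              class = "synthetic_scene")
  })
}

#' Render a synthetic array field with ground truth
#'
#' Simulates one imaged field of a cell monolayer over a printed spot grid:
#' the tracer channel shows filled discs at the layout's spot positions, the
#' nuclei channel one soft-edged blob per cell, and the phenotype channel
#' paints each cell's perinuclear region with a draw from the expressing or
#' silenced intensity distribution (a cell over spot *s* is silenced with
#' probability `per_spot_silenced_fraction[s]`). Signal carries Poisson shot
#' noise; all channels get additive Gaussian background. Bit depth is
#' clipped to 16-bit. Fully deterministic given `seed`.
#'
#' @param params a [scene_params()] with a non-`NULL` layout.
#' @return a `synthetic_scene`: list with `field`
#'   (a [multi_channel_field()]), `truth` (`$cells` data frame and `$spots`
#'   per-spot tally) and the `params` used.
#' @export
render_field <- function(params) render_scene(params, use_layout = TRUE)

#' Render a synthetic well image (no printed spots)
#'
#' As [render_field()] but without a tracer pattern: emulates the well-based
#' (forward transfection) assay where `off_spot_silenced_fraction` governs
#' every cell.
#'
#' @param params a [scene_params()]; any layout is ignored.
#' @return a `synthetic_scene`.
#' @export
render_well <- function(params) {
  params$layout <- NULL
  render_scene(params, use_layout = FALSE)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %d cells, seed %d\n",
              nrow(x$truth$cells), x$params$seed))
  print(x$field)
  invisible(x)
}
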