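# File formats: minimal baseline TIFF (no R TIFF reader exists in this
# stack, so a grayscale 8/16-bit uncompressed subset is implemented here),
# the GenePix Array List (GAL/ATF) dialect for layouts, JSON snapshots and
# CSV tables.

#' Write a grayscale image as an uncompressed baseline TIFF
#'
#' Little-endian, single-sample, photometric black-is-zero, one strip.
#' Values are rounded and clipped to the unsigned range of `bits`.
#'
#' @param img numeric matrix (rows = image rows).
#' @param path output path.
#' @param bits 8 or 16 (default 16).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(img, path, bits = 16L) {
  stopifnot(is.matrix(img))
  if (!bits %in% c(8L, 16L))
    stop_pa("bits must be 8 or 16", class = "phenoarray_bad_arg")
  maxval <- 2^bits - 1
  v <- pmin(maxval, pmax(0, round(as.vector(t(img)))))  # row-major
  h <- nrow(img); w <- ncol(img)
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2,
                              endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4,
                              endian = "little")
  n_entries <- 9L
  ifd_offset <- 8L
  data_offset <- ifd_offset + 2L + n_entries * 12L + 4L
  writeChar("II", con, nchars = 2, eos = NULL)
  wr2(42); wr4(ifd_offset)
  wr2(n_entries)
  entry <- function(tag, type, count, value) {
    wr2(tag); wr2(type); wr4(count)
    if (type == 3L) { wr2(value); wr2(0L) } else wr4(value)
  }
  entry(256L, 4L, 1L, w)                      # ImageWidth
  entry(257L, 4L, 1L, h)                      # ImageLength
  entry(258L, 3L, 1L, bits)                   # BitsPerSample
  entry(259L, 3L, 1L, 1L)                     # Compression = none
  entry(262L, 3L, 1L, 1L)                     # Photometric = BlackIsZero
  entry(273L, 4L, 1L, data_offset)            # StripOffsets
  entry(277L, 3L, 1L, 1L)                     # SamplesPerPixel
  entry(278L, 4L, 1L, h)                      # RowsPerStrip
  entry(279L, 4L, 1L, length(v) * bits / 8)   # StripByteCounts
  wr4(0L)                                     # next IFD = none
  if (bits == 16L) {
    v <- ifelse(v > 32767, v - 65536, v)      # two's complement
    writeBin(as.integer(v), con, size = 2, endian = "little")
  } else {
    writeBin(as.raw(v), con)
  }
  invisible(path)
}

#' Read a grayscale baseline TIFF
#'
#' Supports both byte orders, 8- or 16-bit unsigned single-sample images,
#' no compression, one or more strips.
#'
#' @param path TIFF path.
#' @return integer matrix of pixel values (no rescaling).
#' @export
read_tiff <- function(path) {
  if (!file.exists(path))
    stop_pa("cannot read TIFF '%s': no such file", path,
            class = "phenoarray_io_error")
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L)
    stop_pa("'%s' is not a TIFF (too short)", path,
            class = "phenoarray_io_error")
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM")
    "big" else stop_pa("'%s' is not a TIFF (bad byte order mark)", path,
                       class = "phenoarray_io_error")
  rd <- function(off, size, n = 1L, signed = TRUE)
    readBin(raw[(off + 1L):(off + size * n)], "integer", n = n,
            size = size, endian = endian, signed = signed)
  if (rd(2L, 2L, signed = FALSE) != 42L)
    stop_pa("'%s' is not a TIFF (bad magic)", path,
            class = "phenoarray_io_error")
  ifd <- rd(4L, 4L)
  n_entries <- rd(ifd, 2L, signed = FALSE)
  type_size <- c(`1` = 1L, `3` = 2L, `4` = 4L)
  tags <- list()
  for (i in seq_len(n_entries)) {
    base <- ifd + 2L + (i - 1L) * 12L
    tag <- rd(base, 2L, signed = FALSE)
    type <- rd(base + 2L, 2L, signed = FALSE)
    count <- rd(base + 4L, 4L)
    ts <- type_size[as.character(type)]
    if (is.na(ts)) next   # unsupported value type: ignore the tag
    total <- ts * count
    voff <- if (total <= 4L) base + 8L else rd(base + 8L, 4L)
    vals <- rd(voff, ts, n = count, signed = ts == 4L)
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default))
        stop_pa("TIFF '%s' missing required tag %d", path, tag,
                class = "phenoarray_io_error")
      default
    } else v
  }
  w <- need(256L); h <- need(257L)
  bits <- need(258L, 1L)
  if (need(259L, 1L) != 1L)
    stop_pa("TIFF '%s': only uncompressed images are supported", path,
            class = "phenoarray_io_error")
  if (!need(262L, 1L) %in% c(0L, 1L))
    stop_pa("TIFF '%s': only grayscale images are supported", path,
            class = "phenoarray_io_error")
  if (need(277L, 1L) != 1L || !bits %in% c(8L, 16L))
    stop_pa("TIFF '%s': only single-sample 8/16-bit images are supported",
            path, class = "phenoarray_io_error")
  offsets <- need(273L)
  counts <- need(279L, w * h * bits / 8)
  bytes <- unlist(lapply(seq_along(offsets), function(i)
    raw[(offsets[i] + 1L):(offsets[i] + counts[i])]))
  if (bits == 16L) {
    v <- readBin(bytes, "integer", n = w * h, size = 2L, endian = endian,
                 signed = FALSE)
  } else {
    v <- as.integer(bytes)
  }
  matrix(v, nrow = h, ncol = w, byrow = TRUE)
}

channel_tags <- c(tracer = "560", phenotype = "488", nuclei = "635")

# TRUE if any two centres are closer than min_dist; grid-binned so it is
# linear in the number of spots (layouts can have thousands).
spots_overlap <- function(x, y, min_dist) {
  n <- length(x)
  if (n < 2L) return(FALSE)
  bx <- floor(x / min_dist); by <- floor(y / min_dist)
  bins <- split(seq_len(n), paste(bx, by))
  lookup <- new.env(parent = emptyenv())
  for (key in names(bins)) assign(key, bins[[key]], envir = lookup)
  for (i in seq_len(n)) {
    for (dx in -1:1) for (dy in -1:1) {
      key <- paste(bx[i] + dx, by[i] + dy)
      js <- if (exists(key, envir = lookup, inherits = FALSE))
        get(key, envir = lookup) else next
      js <- js[js > i]
      if (length(js) &&
          any((x[js] - x[i])^2 + (y[js] - y[i])^2 < min_dist^2))
        return(TRUE)
    }
  }
  FALSE
}

#' Write a multi-channel field to disk
#'
#' One 16-bit TIFF per channel, named `<run>_<field>_<tag>.tif` with tags
#' 560 (tracer), 488 (phenotype) and 635 (nuclei), plus a JSON manifest
#' carrying scale and origin metadata.
#'
#' @param field a [multi_channel_field()].
#' @param dir output directory (created if needed).
#' @param run_id,field_id identifiers used in filenames.
#' @return path of the manifest JSON, invisibly.
#' @export
write_field <- function(field, dir, run_id = "run", field_id = "f001") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (ch in names(channel_tags)) {
    fn <- sprintf("%s_%s_%s.tif", run_id, field_id, channel_tags[[ch]])
    write_tiff(field[[ch]], file.path(dir, fn))
    paths[[ch]] <- fn
  }
  manifest <- list(field_id = field_id, run_id = run_id,
                   um_per_pixel = field$um_per_pixel,
                   field_origin = field$field_origin,
                   channels = paths)
  mpath <- file.path(dir, sprintf("%s_%s_manifest.json", run_id, field_id))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Read a multi-channel field from a manifest
#'
#' The manifest (as written by [write_field()]) maps channel names to TIFF
#' paths (relative to the manifest's directory) and carries the pixel scale
#' and field origin. 8- and 16-bit channels may be mixed; values are used
#' as stored, without rescaling.
#'
#' @param manifest_path path to the manifest JSON.
#' @return a [multi_channel_field()].
#' @export
read_field <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  for (ch in names(channel_tags)) {
    if (is.null(m$channels[[ch]]))
      stop_pa("manifest '%s' missing channel '%s'", manifest_path, ch,
              class = "phenoarray_io_error")
  }
  imgs <- lapply(names(channel_tags), function(ch)
    read_tiff(file.path(dir, m$channels[[ch]])))
  names(imgs) <- names(channel_tags)
  shapes <- vapply(imgs, function(x) paste(dim(x), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop_pa("channel shapes differ in '%s': %s", manifest_path,
            paste(names(imgs), shapes, sep = "=", collapse = ", "),
            class = "phenoarray_shape_mismatch")
  multi_channel_field(imgs$tracer, imgs$phenotype, imgs$nuclei,
                      m$um_per_pixel, as.numeric(m$field_origin))
}

#' Validate a field manifest end to end
#'
#' Checks that all three channel files exist, decode, and share one shape.
#' @param manifest_path path to the manifest JSON.
#' @return `TRUE` invisibly (errors otherwise).
#' @export
validate_field_manifest <- function(manifest_path) {
  read_field(manifest_path)
  invisible(TRUE)
}

#' Write / read a grid layout as a GAL-dialect file
#'
#' A tab-delimited ATF ("Axon Text File") array list: header records carry
#' the slide geometry (`SlideWidth`, `SlideHeight`, `SpotDiameter`,
#' `EdgeGap`, `Margin`); data rows are `Block, Row, Column, ID, Name, X, Y`
#' with `Name = "<role>|<reagent_label>"` and coordinates in micrometres
#' (0.1 micrometre precision). The round-trip is lossless at that
#' precision.
#'
#' @param layout a [plan_grid()] layout.
#' @param path file path.
#' @return `write_layout_gal` returns `path` invisibly; `read_layout_gal`
#'   returns a `grid_layout`.
#' @export
write_layout_gal <- function(layout, path) {
  sp <- layout$spots
  header <- c(
    "ATF\t1.0",
    "7\t7",
    "\"Type=GenePix ArrayList V1.0\"",
    "\"BlockCount=1\"",
    sprintf("\"SlideWidth=%g\"", layout$slide_width),
    sprintf("\"SlideHeight=%g\"", layout$slide_height),
    sprintf("\"SpotDiameter=%g\"", layout$spot_diameter),
    sprintf("\"EdgeGap=%g\"", layout$edge_gap),
    sprintf("\"Margin=%g\"", layout$margin),
    paste(c("\"Block\"", "\"Row\"", "\"Column\"", "\"ID\"", "\"Name\"",
            "\"X\"", "\"Y\""), collapse = "\t"))
  name <- paste0(sp$role, "|",
                 ifelse(is.na(sp$reagent_label), "", sp$reagent_label))
  rows <- sprintf("1\t%d\t%d\t\"S%05d\"\t\"%s\"\t%.1f\t%.1f",
                  sp$row, sp$col, sp$spot_id, name,
                  sp$center_x, sp$center_y)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_layout_gal
#' @export
read_layout_gal <- function(path) {
  lines <- readLines(path)
  bad <- function(i, why) stop_pa("malformed GAL '%s' at line %d: %s",
                                  path, i, why,
                                  class = "phenoarray_gal_error")
  if (length(lines) < 3L || !grepl("^ATF", lines[1L]))
    bad(1L, "missing ATF signature")
  dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t")[[1L]]))
  if (length(dims) != 2L || anyNA(dims))
    bad(2L, "expected '<n_header_records>\\t<n_columns>'")
  n_hdr <- dims[1L]
  hdr_lines <- lines[2L + seq_len(n_hdr)]
  geom <- list()
  for (i in seq_along(hdr_lines)) {
    ln <- gsub("\"", "", hdr_lines[i])
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) bad(2L + i, "header record is not key=value")
    geom[[kv[1L]]] <- kv[2L]
  }
  for (key in c("SlideWidth", "SlideHeight", "SpotDiameter", "EdgeGap",
                "Margin"))
    if (is.null(geom[[key]]))
      bad(2L + n_hdr, sprintf("missing geometry record '%s'", key))
  col_line <- 3L + n_hdr
  cols <- gsub("\"", "", strsplit(lines[col_line], "\t")[[1L]])
  need_cols <- c("Block", "Row", "Column", "ID", "Name", "X", "Y")
  if (!all(need_cols %in% cols))
    bad(col_line, paste("missing columns:",
                        paste(setdiff(need_cols, cols), collapse = ", ")))
  data_lines <- lines[seq.int(col_line + 1L, length(lines))]
  data_lines <- data_lines[nzchar(data_lines)]
  parts <- strsplit(data_lines, "\t")
  ix <- match(need_cols, cols)
  get <- function(k) vapply(parts, function(p) gsub("\"", "", p[ix[k]]), "")
  role_label <- strsplit(get(5L), "|", fixed = TRUE)
  role <- vapply(role_label, `[`, "", 1L)
  label <- vapply(role_label, function(x)
    if (length(x) > 1L) x[2L] else "", "")
  spots <- data.frame(
    spot_id = as.integer(sub("^S", "", get(4L))),
    row = as.integer(get(2L)), col = as.integer(get(3L)),
    center_x = as.numeric(get(6L)), center_y = as.numeric(get(7L)),
    reagent_label = ifelse(nzchar(label), label, NA_character_),
    role = role, stringsAsFactors = FALSE)
  if (anyNA(spots$spot_id) || anyNA(spots$center_x) ||
      anyNA(spots$center_y))
    bad(col_line + 1L, "non-numeric id or coordinates in data rows")
  if (anyDuplicated(spots[c("center_x", "center_y")]))
    stop_pa("GAL '%s': duplicate/overlapping spot coordinates", path,
            class = "phenoarray_gal_error")
  spot_diameter <- as.numeric(geom$SpotDiameter)
  if (spots_overlap(spots$center_x, spots$center_y, spot_diameter))
    stop_pa("GAL '%s': spots closer than one diameter (overlap)", path,
            class = "phenoarray_gal_error")
  structure(list(slide_width = as.numeric(geom$SlideWidth),
                 slide_height = as.numeric(geom$SlideHeight),
                 spot_diameter = spot_diameter,
                 edge_gap = as.numeric(geom$EdgeGap),
                 margin = as.numeric(geom$Margin),
                 n_rows = max(spots$row), n_cols = max(spots$col),
                 spots = spots[order(spots$spot_id), , drop = FALSE]),
            class = "grid_layout")
}

#' Write / read a layout as JSON (role/label round-tripping form)
#'
#' @param layout a `grid_layout`.
#' @param path JSON path.
#' @return `read_layout_json` returns a `grid_layout`.
#' @export
write_layout_json <- function(layout, path) {
  jsonlite::write_json(unclass(layout), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$spots <- as.data.frame(x$spots, stringsAsFactors = FALSE)
  structure(x, class = "grid_layout")
}

#' Write pipeline outputs as CSV
#'
#' `write_cells_csv` writes the per-cell table, `write_spot_results_csv`
#' the per-spot tallies, `write_conditions_csv` the normalized per-condition
#' summary (replicate values joined with `;`), and
#' `write_detections_csv` the spot detections.
#'
#' @param x the corresponding data frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cells_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells_csv
#' @export
write_spot_results_csv <- write_cells_csv

#' @rdname write_cells_csv
#' @export
write_detections_csv <- write_cells_csv

#' @rdname write_cells_csv
#' @export
write_conditions_csv <- function(x, path) {
  df <- as.data.frame(x)
  if (!is.null(df$replicates))
    df$replicates <- vapply(df$replicates, function(v)
      paste(format(v, trim = TRUE), collapse = ";"), "")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write ground truth of a synthetic scene
#'
#' Writes the per-cell ground truth CSV, the per-spot truth CSV (field
#' mode) and a JSON snapshot of the scene parameters.
#'
#' @param scene a `synthetic_scene` from [render_field()] /
#'   [render_well()].
#' @param dir output directory.
#' @param run_id,field_id identifiers used in filenames.
#' @return invisibly, the paths written.
#' @export
write_ground_truth <- function(scene, dir, run_id = "run",
                               field_id = "f001") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, sprintf("%s_%s", run_id, field_id))
  paths <- c(cells = paste0(stem, "_truth_cells.csv"))
  write.csv(scene$truth$cells, paths[["cells"]], row.names = FALSE)
  if (!is.null(scene$truth$spots)) {
    paths[["spots"]] <- paste0(stem, "_truth_spots.csv")
    write.csv(scene$truth$spots, paths[["spots"]], row.names = FALSE)
  }
  paths[["params"]] <- paste0(stem, "_params.json")
  p <- unclass(scene$params)
  p$layout <- NULL   # layout is serialized separately as GAL/JSON
  jsonlite::write_json(p, paths[["params"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(paths)
}
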