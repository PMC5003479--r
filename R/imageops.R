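#' Gaussian blur of an intensity image
#'
#' Separable Gaussian filtering with replicate-padded edges. The kernel is
#' truncated at 3 standard deviations.
#'
#' @param img numeric matrix.
#' @param sigma_px standard deviation in pixels; `<= 0` returns `img`
#'   unchanged.
#' @return numeric matrix of the same shape.
#' @export
gaussian_blur <- function(img, sigma_px) {
  stopifnot(is.matrix(img))
  if (sigma_px <= 0) return(img)
  r <- max(1L, as.integer(ceiling(3 * sigma_px)))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  blur1 <- function(m) {
    nr <- nrow(m)
    padded <- m[c(rep(1L, r), seq_len(nr), rep(nr, r)), , drop = FALSE]
    f <- stats::filter(padded, k, sides = 2)
    matrix(f[(r + 1L):(r + nr), ], nrow = nr)
  }
  t(blur1(t(blur1(img))))
}

#' Otsu's threshold
#'
#' Maximizes between-class variance over a binned histogram of the values.
#' Returns the bin-centre threshold; pixels strictly above it are foreground.
#'
#' @param x numeric vector or matrix of intensities.
#' @param n_bins histogram resolution (default 256).
#' @return a single numeric threshold. If all values are equal the common
#'   value itself is returned (so `x > otsu(x)` selects nothing).
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop_pa("no finite values for Otsu threshold",
                               class = "phenoarray_empty_input")
  lo <- min(x); hi <- max(x)
  if (lo == hi) return(lo)
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- as.numeric(tabulate(
    findInterval(x, breaks, rightmost.closed = TRUE), nbins = n_bins))
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w <- cumsum(counts)
  mu <- cumsum(counts * mids)
  n <- w[n_bins]; mu_t <- mu[n_bins]
  w0 <- w[-n_bins]; mu0 <- mu[-n_bins]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, n_bins - 1L)
  between[valid] <- (mu_t * w0[valid] - n * mu0[valid])^2 /
    (w0[valid] * w1[valid])
  # the criterion is flat across an empty gap between modes: take the
  # middle of the maximal plateau rather than its lower edge
  best <- which(between == max(between))
  breaks[as.integer(round(stats::median(best))) + 1L]
}

#' Label connected components of a binary mask
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix; 0 = background, components numbered from 1 in
#'   raster order.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  if (!connectivity %in% c(4L, 8L))
    stop_pa("connectivity must be 4 or 8", class = "phenoarray_bad_arg")
  storage.mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  .cc_label(mask, as.integer(connectivity))
}

#' Fill holes in a binary mask
#'
#' A hole is a background component not connected (4-connectivity) to the
#' image border.
#'
#' @param mask logical matrix.
#' @return logical matrix with holes set to `TRUE`.
#' @export
fill_holes <- function(mask) {
  storage.mode(mask) <- "logical"
  bg <- .cc_label(!mask, 4L)
  border <- unique(c(bg[1L, ], bg[nrow(bg), ], bg[, 1L], bg[, ncol(bg)]))
  border <- border[border > 0L]
  mask | (bg > 0L & !(bg %in% border))
}

#' Euclidean distance transform
#'
#' Exact distance of every foreground pixel to the nearest background pixel.
#'
#' @param mask logical matrix.
#' @return numeric matrix of distances in pixels (0 on background).
#' @export
distance_transform <- function(mask) {
  storage.mode(mask) <- "logical"
  sqrt(.edt_sq(mask))
}

# Plateau-aware local maxima of `img` within `mask`, grouped so that maxima
# closer than `min_dist_px` collapse to a single marker. Returns an integer
# marker image for the watershed.
find_markers <- function(img, mask, min_dist_px) {
  r <- max(1L, as.integer(round(min_dist_px)))
  wm <- .window_max(img, r)
  cand <- mask & img >= wm & img > 0
  if (!any(cand)) return(matrix(0L, nrow(img), ncol(img)))
  # candidate maxima form plateaus; connected candidates are one marker
  groups <- .cc_label(cand, 8L)
  markers <- matrix(0L, nrow(img), ncol(img))
  idx <- which(cand)
  grp <- groups[idx]
  best <- vapply(split(idx, grp), function(ii) ii[which.max(img[ii])], 0L)
  markers[best] <- seq_along(best)
  markers
}

#' Marker-based watershed region growing
#'
#' Grows regions from marker pixels in increasing altitude order, restricted
#' to the mask (no watershed lines; every mask pixel reachable from a marker
#' is assigned).
#'
#' @param altitude numeric matrix; lower altitude floods first.
#' @param mask logical matrix restricting the flood.
#' @param markers integer matrix of seed labels (> 0).
#' @return integer label matrix.
#' @export
watershed_regions <- function(altitude, mask, markers) {
  storage.mode(mask) <- "logical"
  storage.mode(markers) <- "integer"
  .priority_flood(altitude, mask, markers)
}

#' Expand labels by a bounded radius, keeping regions disjoint
#'
#' Every unlabelled pixel within `radius_px` of a labelled pixel receives the
#' nearest label (nearest-label dilation). Used for the perinuclear
#' measurement region.
#'
#' @param labels integer label matrix.
#' @param radius_px dilation radius in pixels.
#' @return integer label matrix.
#' @export
expand_labels <- function(labels, radius_px) {
  storage.mode(labels) <- "integer"
  .nearest_label_within(labels, as.numeric(radius_px))
}

# Guard for automatic (Otsu) thresholding on signal-free images: a genuine
# foreground must stand clear of the background noise. Otsu always splits a
# distribution, even pure read noise; requiring the class means to separate
# by > 3 background standard deviations rejects that case while real
# fluorescence signal (tens of noise SDs above background) passes easily.
has_contrast <- function(img, mask, k = 3) {
  fg <- img[mask]
  bg <- img[!mask]
  if (length(fg) == 0L || length(bg) < 2L) return(FALSE)
  (mean(fg) - mean(bg)) > k * stats::sd(bg)
}

# Per-label region properties: area, centroid (1-based row/col), mean of an
# optional intensity image.
region_props <- function(labels, intensity = NULL) {
  n <- max(labels)
  if (n == 0L) {
    return(data.frame(label = integer(), area_px = integer(),
                      row = numeric(), col = numeric(),
                      mean_intensity = numeric()))
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  nr <- nrow(labels)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  area <- tabulate(lab, nbins = n)
  sum_r <- rowsum(as.numeric(rows), lab)
  sum_c <- rowsum(as.numeric(cols), lab)
  present <- sort(unique(lab))
  out <- data.frame(label = present,
                    area_px = area[present],
                    row = as.numeric(sum_r[, 1L]) / area[present],
                    col = as.numeric(sum_c[, 1L]) / area[present])
  if (!is.null(intensity)) {
    sum_i <- rowsum(as.numeric(intensity[idx]), lab)
    out$mean_intensity <- as.numeric(sum_i[, 1L]) / area[present]
  }
  out
}
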