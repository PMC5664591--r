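#' White-reference panel
#'
#' The detected white reflectance standard: a pixel mask, a per-column
#' usability flag (columns occluded by posts or leaves are flagged
#' invalid and contribute nothing to any normalisation), and the mean
#' tile spectrum of each valid column.
#'
#' @param mask logical matrix marking tile pixels.
#' @param cube the [hypercube()] the mask was detected in.
#' @param column_valid logical per column; defaults to mask occupancy.
#' @return A `whiteref_panel`: list with `mask`, `column_valid` and
#'   `spectra` (matrix `[column, band]`, `NA` rows for invalid columns).
#' @export
whiteref_panel <- function(mask, cube, column_valid = NULL) {
  stopifnot_cube(cube)
  validate_mask(mask, cube)
  occupancy <- colSums(mask) > 0L
  if (is.null(column_valid)) column_valid <- occupancy
  column_valid <- column_valid & occupancy
  d <- dim(cube$data)
  spectra <- matrix(NA_real_, d[2], d[3])
  npx <- colSums(mask)
  for (b in seq_len(d[3])) {
    s <- colSums(cube$data[, , b] * mask)
    spectra[, b] <- ifelse(npx > 0L, s / npx, NA_real_)
  }
  spectra[!column_valid, ] <- NA_real_
  structure(list(mask = mask, column_valid = column_valid, spectra = spectra),
            class = "whiteref_panel")
}

#' @export
print.whiteref_panel <- function(x, ...) {
  cat(sprintf("<whiteref_panel> %d/%d valid columns, %d mask pixels\n",
              sum(x$column_valid), length(x$column_valid), sum(x$mask)))
  invisible(x)
}

#' Detect the white reference in a VNIR cube
#'
#' Works on the mean intensity over 455-480 nm, a bright region with the
#' best contrast between the tile and its surroundings. The bottom edge of
#' the tile (bright above, dark below) is traced first with the plain edge
#' cost; a V-shaped distance penalty built from that edge and the tile's
#' expected width then guides a second seam to the top edge. Pixels
#' strictly between the two seams form the initial mask, which is passed
#' through [filter_occluded_columns()].
#'
#' @param cube a VNIR [hypercube()].
#' @param expected_width expected tile width in pixels (known a priori
#'   from the imaging geometry).
#' @param lambda_ver vertical move penalty for both seams.
#' @param lambda_dist weight of the distance penalty for the top seam.
#' @return A [whiteref_panel()] (occlusion-filtered), with attributes
#'   `top` and `bottom` holding the two seams.
#' @export
detect_whiteref_vnir <- function(cube, expected_width, lambda_ver = 0.05,
                                 lambda_dist = 0.01) {
  stopifnot_cube(cube)
  img <- band_mean(cube, band_range(455, 480))
  bottom <- min_cost_path(cost_edge(img, polarity = "falling"), lambda_ver)
  d <- shape_function_from_edge(bottom, expected_width, nrow(img))
  top <- min_cost_path(cost_edge_with_shape(img, d, lambda_dist, polarity = "rising"),
                       lambda_ver)
  if (mean(top$y < bottom$y) < 0.5)
    detection_error("white-reference detection failed: top edge not above bottom edge")
  rows <- row(img)
  mask <- sweep(rows, 2L, top$y, `>`) & sweep(rows, 2L, bottom$y, `<`)
  panel <- whiteref_panel(mask, cube)
  panel <- filter_occluded_columns(panel, img)
  attr(panel, "top") <- top
  attr(panel, "bottom") <- bottom
  panel
}

#' Remove occluded columns from a white-reference panel
#'
#' The tile is nominally uniform down each column, so two rules flag
#' occlusions. First, the variance of the intensity image over the mask
#' rows of each column is computed and columns with variance above twice
#' the mean column variance are invalidated (partial occlusions by leaves
#' create mixed bright/dark columns). Second, columns whose mean intensity
#' falls below 80% of the median of the remaining columns are invalidated
#' (full occlusions by posts or leaves are uniformly dark, and a
#' median-relative cut is robust to global illumination drift).
#'
#' @param panel a [whiteref_panel()].
#' @param img the scalar intensity image the panel was detected in.
#' @param dark_fraction darkness cut relative to the median valid-column
#'   mean (default 0.8).
#' @return The panel with `column_valid` updated and invalid spectra set
#'   to `NA`.
#' @export
filter_occluded_columns <- function(panel, img, dark_fraction = 0.8) {
  if (!inherits(panel, "whiteref_panel")) stop("expected a `whiteref_panel`", call. = FALSE)
  valid <- panel$column_valid
  n <- length(valid)
  col_var <- rep(NA_real_, n)
  col_mean <- rep(NA_real_, n)
  for (x in which(valid)) {
    px <- img[panel$mask[, x], x]
    col_var[x] <- if (length(px) > 1L) stats::var(px) else 0
    col_mean[x] <- mean(px)
  }
  mv <- mean(col_var[valid])
  if (is.finite(mv) && mv >= 0)
    valid[valid] <- col_var[valid] <= 2 * mv
  if (any(valid)) {
    med <- stats::median(col_mean[valid])
    valid[valid] <- col_mean[valid] >= dark_fraction * med
  }
  if (!any(valid))
    detection_error("white-reference detection failed: every column was invalidated")
  panel$column_valid <- valid
  panel$spectra[!valid, ] <- NA_real_
  panel
}

#' Detect the white reference in a SWIR cube
#'
#' The normalised difference of 3 bands centred at 1620 nm versus 1537 nm
#' separates the tile, which forms the lowest mode of the index histogram,
#' from background and plants. The histogram (256 bins, smoothed with a
#' 5-bin moving average) is searched for a local minimum starting from the
#' bin holding the 10% pixel quantile, walking outward to the nearest bin
#' strictly lower than both neighbours. The index image is thresholded at
#' that minimum (tile = pixels below), eroded with the 3x3 cross to drop
#' stray detections, and column validity follows mask occupancy.
#'
#' @param cube a SWIR [hypercube()] (dark-corrected).
#' @return A [whiteref_panel()], with attribute `threshold`.
#' @export
detect_whiteref_swir <- function(cube) {
  stopifnot_cube(cube)
  pre <- index_preset("whiteref_swir")
  img <- normalized_difference(cube, pre$w_a, pre$w_b)
  thr <- histogram_local_minimum(img, start_quantile = 0.10)
  mask <- erode_cross(img < thr)
  if (!any(mask))
    detection_error("white-reference detection failed: empty mask after erosion")
  panel <- whiteref_panel(mask, cube)
  attr(panel, "threshold") <- thr
  panel
}

#' Histogram local-minimum threshold
#'
#' Builds a fixed-bin histogram of the image, smooths it with a moving
#' average, and walks outward from the bin containing the given pixel
#' quantile to the nearest bin strictly lower than both its neighbours
#' (right neighbour tried first on distance ties). Returns that bin's
#' centre value.
#'
#' @param img numeric matrix.
#' @param start_quantile pixel quantile seeding the search (default 0.10).
#' @param n_bins histogram bins (default 256).
#' @param smooth moving-average window in bins (default 5).
#' @return The threshold value.
#' @export
histogram_local_minimum <- function(img, start_quantile = 0.10, n_bins = 256L,
                                    smooth = 5L) {
  v <- as.vector(img)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("cannot threshold a constant image", call. = FALSE)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), n_bins),
                nbins = n_bins)
  s <- as.numeric(stats::filter(h, rep(1 / smooth, smooth), sides = 2L))
  s[is.na(s)] <- h[is.na(s)]
  ## a local minimum is a maximal run of equal smoothed counts flanked on
  ## both sides by strictly greater values; the run's centre bin marks it
  is_min <- logical(n_bins)
  i <- 1L
  while (i <= n_bins) {
    j <- i
    while (j < n_bins && s[j + 1L] == s[i]) j <- j + 1L
    if (i > 1L && j < n_bins && s[i - 1L] > s[i] && s[j + 1L] > s[i])
      is_min[(i + j) %/% 2L] <- TRUE
    i <- j + 1L
  }
  q <- stats::quantile(v, start_quantile, names = FALSE)
  start <- min(max(findInterval(q, edges, rightmost.closed = TRUE), 1L), n_bins)
  for (dist in 0:(n_bins - 1L)) {
    for (j in unique(c(start + dist, start - dist))) {
      if (j >= 1L && j <= n_bins && is_min[j])
        return((edges[j] + edges[j + 1L]) / 2)
    }
  }
  detection_error("histogram has no interior local minimum (unimodal image?)")
}
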