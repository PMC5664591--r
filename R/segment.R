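#' Threshold an image into a binary mask
#'
#' Strict inequality: `mask = img > thr`.
#'
#' @param img numeric matrix `[y, x]`.
#' @param thr threshold value.
#' @return Logical matrix.
#' @export
threshold_mask <- function(img, thr) {
  if (!is.matrix(img)) stop("image must be a matrix", call. = FALSE)
  img > thr
}

#' Binary erosion with a 3x3 cross
#'
#' A pixel survives only if it and its four 4-connected neighbours are all
#' true. Neighbours outside the image count as false, so border pixels are
#' removed unless fully supported — a conservative rule that also drops
#' the mixed pixels found on leaf edges. Single stray detections are
#' always removed.
#'
#' @param mask logical matrix.
#' @return Logical matrix of the same shape.
#' @export
erode_cross <- function(mask) {
  validate_mask(mask)
  m <- nrow(mask); n <- ncol(mask)
  up    <- rbind(FALSE, mask[-m, , drop = FALSE])
  down  <- rbind(mask[-1L, , drop = FALSE], FALSE)
  left  <- cbind(FALSE, mask[, -n, drop = FALSE])
  right <- cbind(mask[, -1L, drop = FALSE], FALSE)
  mask & up & down & left & right
}

#' Otsu's threshold
#'
#' Histogram thresholding maximising the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` over a 256-bin histogram spanning the image
#' range. The returned value is the bin edge separating the two classes;
#' use it with a strict `>` comparison ([threshold_mask()]). Ties go to
#' the lowest qualifying edge.
#'
#' @param img numeric matrix with at least two distinct values.
#' @param n_bins number of histogram bins (default 256).
#' @return The threshold value.
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  v <- as.vector(img)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("cannot threshold a constant image", call. = FALSE)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  num <- (mu_t * w0 - mu)^2
  den <- w0 * w1
  sigma_b <- ifelse(den > 0, num / den, -Inf)
  k <- which.max(sigma_b[-n_bins])  # split after bin k; ties -> lowest edge
  edges[k + 1L]
}

#' Plant-segmentation parameters
#'
#' @param ndvi_threshold fixed NDVI cut in (-1, 1) separating leaf pixels
#'   from background; the conventional vegetation cut-off 0.3 by default.
#' @param swir_bottom_crop_fraction fraction of image rows removed from
#'   the bottom of SWIR masks (grass removal), in `[0, 1)`.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(ndvi_threshold = 0.3,
                                swir_bottom_crop_fraction = 0.15) {
  if (!(ndvi_threshold > -1 && ndvi_threshold < 1))
    stop("`ndvi_threshold` must lie in (-1, 1)", call. = FALSE)
  if (!(swir_bottom_crop_fraction >= 0 && swir_bottom_crop_fraction < 1))
    stop("`swir_bottom_crop_fraction` must lie in [0, 1)", call. = FALSE)
  structure(list(ndvi_threshold = ndvi_threshold,
                 swir_bottom_crop_fraction = swir_bottom_crop_fraction),
            class = "segmentation_params")
}

#' Detect plant material in a VNIR cube
#'
#' NDVI is thresholded at a fixed value, the mask is eroded with the 3x3
#' cross to drop stray and mixed pixels, and the grass strip is removed:
#' a minimum-cost seam over `exp(-I(x)) * (1 - g_y)` traces the bottom of
#' the cardboard background across the NDVI image, and every pixel below
#' the seam is cleared.
#'
#' @param cube a VNIR [hypercube()].
#' @param params a [segmentation_params()].
#' @param lambda_ver vertical move penalty for the seam.
#' @return List with `mask` (logical matrix) and `boundary`
#'   (the grass-boundary [min_cost_path()] seam).
#' @export
detect_plants_vnir <- function(cube, params = segmentation_params(),
                               lambda_ver = 0.05) {
  nd <- ndvi(cube)
  mask <- erode_cross(threshold_mask(nd, params$ndvi_threshold))
  boundary <- min_cost_path(cost_grass_boundary(nd), lambda_ver)
  rows <- row(mask)
  below <- sweep(rows, 2L, boundary$y, `>`)
  mask[below] <- FALSE
  list(mask = mask, boundary = boundary)
}

#' Detect plant material in a SWIR cube
#'
#' The water-absorption index (3 bands at 1375 nm vs 3 at 1411 nm) is
#' thresholded with Otsu's method; leaf water absorption at 1411 nm gives
#' vegetation a high index while dry materials sit near zero. Horizontal
#' striping noise in SWIR images makes a seam-based grass boundary
#' unreliable, so a fixed fraction of bottom rows is cleared instead.
#'
#' @param cube a SWIR [hypercube()] (dark-corrected).
#' @param params a [segmentation_params()].
#' @return List with `mask` (logical matrix), `threshold` (the Otsu value)
#'   and `crop_rows` (number of bottom rows cleared).
#' @export
detect_plants_swir <- function(cube, params = segmentation_params()) {
  pre <- index_preset("plant_swir")
  img <- normalized_difference(cube, pre$w_a, pre$w_b)
  thr <- otsu_threshold(img)
  mask <- threshold_mask(img, thr)
  h <- nrow(mask)
  crop_rows <- floor(params$swir_bottom_crop_fraction * h)
  if (crop_rows > 0L) mask[(h - crop_rows + 1L):h, ] <- FALSE
  list(mask = mask, threshold = thr, crop_rows = crop_rows)
}
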