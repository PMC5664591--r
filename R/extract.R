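#' Sectioned white-reference normalisation to reflectance
#'
#' Illumination changes along the travel direction, so the image is
#' divided into consecutive column sections of fixed width and every pixel
#' spectrum in a section is divided by the mean white-reference spectrum
#' of that section (mean over the panel's valid columns inside it).
#' Sections left without any valid reference column borrow the spectrum of
#' the nearest section that has one (ties to the left). Reflectance is not
#' clipped at 1: specular pixels legitimately exceed the tile.
#'
#' @param cube a [hypercube()] in sensor units.
#' @param panel the [whiteref_panel()] detected in the same cube.
#' @param section_width_px section width in columns (default 100).
#' @return A `hypercube` with `kind = "reflectance"`.
#' @export
normalize_reflectance <- function(cube, panel, section_width_px = 100L) {
  stopifnot_cube(cube)
  if (!inherits(panel, "whiteref_panel")) stop("expected a `whiteref_panel`", call. = FALSE)
  if (section_width_px < 1L) stop("`section_width_px` must be >= 1", call. = FALSE)
  if (!any(panel$column_valid))
    stop("white-reference panel has no valid columns", call. = FALSE)
  d <- dim(cube$data)
  section_of <- ((seq_len(d[2]) - 1L) %/% section_width_px) + 1L
  n_sec <- max(section_of)
  ref <- matrix(NA_real_, n_sec, d[3])
  has_ref <- logical(n_sec)
  for (s in seq_len(n_sec)) {
    cols <- which(section_of == s & panel$column_valid)
    if (length(cols) > 0L) {
      ref[s, ] <- colMeans(panel$spectra[cols, , drop = FALSE])
      has_ref[s] <- TRUE
    }
  }
  src <- which(has_ref)
  for (s in which(!has_ref)) {
    nearest <- src[order(abs(src - s), src)][1L]  # tie -> left (lower index)
    ref[s, ] <- ref[nearest, ]
  }
  zero_band <- which(apply(ref == 0, 2L, any))
  if (length(zero_band) > 0L)
    stop(sprintf("white-reference spectrum is zero in band %d (%.1f nm)",
                 zero_band[1L], cube$wavelengths_nm[zero_band[1L]]), call. = FALSE)
  out <- cube$data
  for (b in seq_len(d[3])) {
    out[, , b] <- out[, , b] / rep(ref[section_of, b], each = d[1])
  }
  hypercube(out, cube$wavelengths_nm, kind = "reflectance")
}

region_cols <- function(region, width) {
  a <- region$analysis_start; e <- region$analysis_end
  if (e <= a) stop("empty analysis span", call. = FALSE)
  if (a < 0 || e > width) stop("analysis span outside image", call. = FALSE)
  (a + 1L):e
}

#' Plant height from the binary mask
#'
#' Vertical extent of the plant mask within the region's analysis span:
#' `height_px = lowest true row - highest true row + 1` (0 if the span is
#' empty). The metric height uses the scanner's swath calibration
#' (`height_m = height_px * swath_m / swath_px`); at the VNIR defaults a
#' full-height column of 402 px spans 1.2 m.
#'
#' @param mask logical plant mask.
#' @param region one row of a [split_row()] data frame.
#' @param swath_m,swath_px vertical swath calibration (default 1.2 m over
#'   402 px).
#' @return List with `height_px` and `height_m`.
#' @export
plant_height <- function(mask, region, swath_m = 1.2, swath_px = 402L) {
  validate_mask(mask)
  sub <- mask[, region_cols(region, ncol(mask)), drop = FALSE]
  rows <- which(rowSums(sub) > 0L)
  height_px <- if (length(rows) == 0L) 0L else max(rows) - min(rows) + 1L
  list(height_px = as.integer(height_px),
       height_m = height_px * swath_m / swath_px)
}

#' Plant density from the binary mask
#'
#' Mean number of plant pixels per column within the region's analysis
#' span — the image-derived counterpart of a visual cane-density score.
#'
#' @inheritParams plant_height
#' @return Mean plant pixels per column (float).
#' @export
plant_density <- function(mask, region) {
  validate_mask(mask)
  cols <- region_cols(region, ncol(mask))
  sum(mask[, cols]) / length(cols)
}

#' Mean reflectance spectrum of one plant
#'
#' Per-band mean over the plant-mask pixels inside the region's analysis
#' span.
#'
#' @param refl_cube a reflectance [hypercube()].
#' @param mask logical plant mask.
#' @param region one row of a [split_row()] data frame.
#' @return Numeric vector, one value per band.
#' @export
plant_mean_spectrum <- function(refl_cube, mask, region) {
  stopifnot_cube(refl_cube)
  validate_mask(mask, refl_cube)
  cols <- region_cols(region, ncol(mask))
  sub <- mask[, cols, drop = FALSE]
  n_px <- sum(sub)
  if (n_px == 0L)
    stop(sprintf("no plant pixels in region %s", region$plant_id), call. = FALSE)
  d <- dim(refl_cube$data)
  vapply(seq_len(d[3]), function(b) {
    sl <- refl_cube$data[, cols, b]
    sum(sl[sub]) / n_px
  }, numeric(1))
}

#' Extract traits and spectra for every plant region
#'
#' @param refl_cube reflectance [hypercube()].
#' @param mask plant mask.
#' @param regions data frame from [split_row()].
#' @param swath_m,swath_px swath calibration for heights.
#' @return List with `traits` (data frame: plant_id, height_px, height_m,
#'   density, n_pixels) and `spectra` (matrix `[plant, band]`, `NA` rows
#'   for plants without pixels).
#' @export
extract_plant_data <- function(refl_cube, mask, regions, swath_m = 1.2,
                               swath_px = nrow(mask)) {
  d <- dim(refl_cube$data)
  n <- nrow(regions)
  traits <- data.frame(plant_id = regions$plant_id, height_px = 0L,
                       height_m = 0, density = 0, n_pixels = 0L)
  spectra <- matrix(NA_real_, n, d[3])
  for (i in seq_len(n)) {
    reg <- regions[i, ]
    h <- plant_height(mask, reg, swath_m, swath_px)
    traits$height_px[i] <- h$height_px
    traits$height_m[i] <- h$height_m
    traits$density[i] <- plant_density(mask, reg)
    cols <- region_cols(reg, ncol(mask))
    n_px <- sum(mask[, cols])
    traits$n_pixels[i] <- n_px
    if (n_px > 0L) spectra[i, ] <- plant_mean_spectrum(refl_cube, mask, reg)
  }
  list(traits = traits, spectra = spectra)
}
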