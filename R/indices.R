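#' Band windows
#'
#' A band window selects the cube bands averaged by [band_mean()]. Two
#' modes exist: `range` keeps every band whose centre wavelength lies in
#' `[lo_nm, hi_nm]` (endpoints inclusive), and `centred` keeps the
#' `n_bands` bands whose centres are nearest `centre_nm` (nearest-neighbour
#' selection, so an exact wavelength need not exist on the scanner's band
#' grid).
#'
#' @param lo_nm,hi_nm range limits in nm, `lo_nm < hi_nm`.
#' @param centre_nm centre wavelength in nm.
#' @param n_bands odd number of bands to average, >= 1.
#' @return A `band_window` object.
#' @export
band_range <- function(lo_nm, hi_nm) {
  if (!(lo_nm < hi_nm)) stop("`lo_nm` must be < `hi_nm`", call. = FALSE)
  structure(list(mode = "range", lo_nm = lo_nm, hi_nm = hi_nm), class = "band_window")
}

#' @rdname band_range
#' @export
band_centred <- function(centre_nm, n_bands = 3L) {
  n_bands <- as.integer(n_bands)
  if (n_bands < 1L || n_bands %% 2L == 0L)
    stop("`n_bands` must be odd and >= 1", call. = FALSE)
  structure(list(mode = "centred", centre_nm = centre_nm, n_bands = n_bands),
            class = "band_window")
}

resolve_window <- function(cube, w) {
  if (!inherits(w, "band_window")) stop("expected a `band_window`", call. = FALSE)
  wl <- cube$wavelengths_nm
  if (w$mode == "range") {
    idx <- which(wl >= w$lo_nm & wl <= w$hi_nm)
    if (length(idx) == 0L)
      stop(sprintf("no band centre falls in [%g, %g] nm (cube spans %g-%g nm)",
                   w$lo_nm, w$hi_nm, min(wl), max(wl)), call. = FALSE)
  } else {
    if (w$centre_nm < min(wl) - (max(wl) - min(wl)) || w$centre_nm > max(wl) + (max(wl) - min(wl)))
      stop(sprintf("centre %g nm is far outside the cube's range %g-%g nm",
                   w$centre_nm, min(wl), max(wl)), call. = FALSE)
    idx <- order(abs(wl - w$centre_nm))[seq_len(min(w$n_bands, length(wl)))]
    idx <- sort(idx)
  }
  idx
}

#' Mean-intensity image over a band window
#'
#' Per-pixel arithmetic mean of the selected bands, always in floating
#' point. This is the single-channel image that all segmentation steps
#' work on: operating on a few averaged bands keeps memory low and lets
#' ordinary machine-vision methods be applied to hyperspectral data.
#'
#' @param cube a [hypercube()].
#' @param w a [band_range()] or [band_centred()] window.
#' @return Numeric matrix `[y, x]`.
#' @export
band_mean <- function(cube, w) {
  stopifnot_cube(cube)
  idx <- resolve_window(cube, w)
  d <- dim(cube$data)
  sl <- cube$data[, , idx, drop = FALSE]
  out <- matrix(rowSums(matrix(as.numeric(sl), d[1] * d[2], length(idx))) / length(idx),
                d[1], d[2])
  out
}

#' Normalised-difference index image
#'
#' Computes `(A - B) / (A + B)` with `A = band_mean(cube, w_a)` and
#' `B = band_mean(cube, w_b)`. Pixels where `A + B == 0` carry no
#' contrast and are set to 0, so the output is finite everywhere and lies
#' in `[-1, 1]`. Swapping the windows negates the image.
#'
#' @param cube a [hypercube()].
#' @param w_a,w_b band windows for the two terms.
#' @return Numeric matrix `[y, x]` in `[-1, 1]`.
#' @export
normalized_difference <- function(cube, w_a, w_b) {
  a <- band_mean(cube, w_a)
  b <- band_mean(cube, w_b)
  s <- a + b
  out <- (a - b) / s
  out[s == 0] <- 0
  out[!is.finite(out)] <- 0
  out
}

#' Normalised difference vegetation index (NDVI)
#'
#' `NDVI = (IR - red) / (IR + red)` with red the mean intensity over
#' 650-680 nm and IR the mean over 710-740 nm (band centres inclusive of
#' the endpoints). High for green vegetation, near zero for the cardboard
#' background.
#'
#' @param cube a VNIR [hypercube()] covering both wavelength windows.
#' @return Numeric matrix `[y, x]` in `[-1, 1]`.
#' @export
ndvi <- function(cube) {
  normalized_difference(cube, band_range(710, 740), band_range(650, 680))
}

#' Preset index windows
#'
#' Named window pairs used by the pipeline:
#' * `plant_swir`: 3 bands centred at 1375 nm vs 3 at 1411 nm. Leaf water
#'   absorption depresses 1411 nm relative to 1375 nm, so vegetation
#'   scores high while dry background materials score near zero.
#' * `whiteref_swir`: 3 bands centred at 1620 nm vs 3 at 1537 nm; the
#'   white reference tile forms the low mode of this index.
#'
#' @param name `"plant_swir"` or `"whiteref_swir"`.
#' @return List with elements `w_a`, `w_b`.
#' @export
index_preset <- function(name = c("plant_swir", "whiteref_swir")) {
  name <- match.arg(name)
  switch(name,
    plant_swir = list(w_a = band_centred(1375, 3), w_b = band_centred(1411, 3)),
    whiteref_swir = list(w_a = band_centred(1620, 3), w_b = band_centred(1537, 3)))
}
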