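#' Subtract a per-row dark-current spectrum
#'
#' Push-broom scanners read one vertical line at a time, so the dark
#' current is specific to each vertical detector element: the correction is
#' a `rows x bands` matrix subtracted from every column of the cube.
#' Results are clamped at zero, since negative intensities are unphysical
#' and destabilise the normalised-difference indices computed downstream.
#' SWIR cubes need this correction; VNIR dark current is typically small
#' enough to skip, but any cube is accepted.
#'
#' @param cube a [hypercube()].
#' @param dark numeric matrix `[row, band]` matching the cube's height and
#'   band count (one dark spectrum per vertical pixel).
#' @return A `hypercube` with `kind = "dark_corrected"`.
#' @export
subtract_dark_current <- function(cube, dark) {
  stopifnot_cube(cube)
  d <- dim(cube$data)
  if (!is.matrix(dark) || nrow(dark) != d[1] || ncol(dark) != d[3])
    stop(sprintf("dark spectrum must be a %d x %d matrix [row, band]", d[1], d[3]),
         call. = FALSE)
  out <- cube$data
  for (b in seq_len(d[3])) {
    out[, , b] <- pmax(out[, , b] - dark[, b], 0)
  }
  hypercube(out, cube$wavelengths_nm, kind = "dark_corrected")
}

#' Read a dark-current spectrum
#'
#' Accepts either an ENVI raster of shape `rows x 1 x bands` or a CSV with
#' columns `row`, `band`, `value` (1-based indices).
#'
#' @param path file path (`.csv` or ENVI data file).
#' @return Numeric matrix `[row, band]`.
#' @export
read_dark_spectrum <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path)
    need <- c("row", "band", "value")
    if (!all(need %in% names(df)))
      stop("dark CSV must have columns row, band, value", call. = FALSE)
    m <- matrix(0, max(df$row), max(df$band))
    m[cbind(df$row, df$band)] <- df$value
    m
  } else {
    cube <- read_cube(path)
    d <- dim(cube$data)
    if (d[2] != 1L)
      stop("dark spectrum raster must have exactly 1 column (rows x 1 x bands)",
           call. = FALSE)
    matrix(cube$data[, 1L, ], d[1], d[3])
  }
}

#' Crop the ends of a row image
#'
#' The first and last few metres of a scanned row contain equipment and
#' turning space rather than plants; they are removed by restricting the
#' cube to a half-open column interval `[start_x, end_x)` in 0-based
#' coordinates (column 0 is the row start). After this single explicit
#' crop no manual intervention is needed anywhere in the pipeline.
#'
#' @param cube a [hypercube()].
#' @param start_x first column kept (0-based, inclusive).
#' @param end_x first column dropped (0-based, exclusive); must satisfy
#'   `0 <= start_x < end_x <= width`.
#' @return The cropped `hypercube` (same kind).
#' @export
crop_row_ends <- function(cube, start_x, end_x) {
  stopifnot_cube(cube)
  width <- dim(cube$data)[2]
  if (start_x < 0 || end_x > width || start_x >= end_x)
    stop(sprintf("invalid crop interval [%s, %s) for width %d", start_x, end_x, width),
         call. = FALSE)
  cols <- (start_x + 1L):end_x
  hypercube(cube$data[, cols, , drop = FALSE], cube$wavelengths_nm, kind = cube$kind)
}
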