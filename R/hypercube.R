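#' Construct a hyperspectral cube
#'
#' The core raster container of the package: a 3-D intensity array indexed
#' `[y, x, band]` together with the per-band centre wavelengths in
#' nanometres. `y` is the vertical (scan-line) axis with row 1 at the top;
#' `x` is the horizontal travel axis with column 1 at the row start. Values
#' are in arbitrary sensor units (digital numbers) for `kind = "raw"` or
#' `"dark_corrected"`, and dimensionless ratios for `kind = "reflectance"`
#' (which may exceed 1 for specular pixels).
#'
#' @param data numeric 3-D array `[y, x, band]`, every dimension >= 1.
#' @param wavelengths_nm numeric vector of strictly increasing band centre
#'   wavelengths (nm); length must equal `dim(data)[3]`.
#' @param kind one of `"raw"`, `"dark_corrected"`, `"reflectance"`.
#' @return An object of class `hypercube`: a list with elements `data`,
#'   `wavelengths_nm` and `kind`.
#' @examples
#' cube <- hypercube(array(1, dim = c(4, 5, 3)), c(450, 550, 650))
#' dim(cube$data)
#' @export
hypercube <- function(data, wavelengths_nm, kind = c("raw", "dark_corrected", "reflectance")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array [y, x, band]", call. = FALSE)
  if (any(dim(data) < 1L))
    stop("all cube dimensions must be >= 1", call. = FALSE)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (length(wavelengths_nm) != dim(data)[3L])
    stop(sprintf("wavelength count (%d) does not match band count (%d)",
                 length(wavelengths_nm), dim(data)[3L]), call. = FALSE)
  if (length(wavelengths_nm) > 1L && any(diff(wavelengths_nm) <= 0))
    stop("`wavelengths_nm` must be strictly increasing", call. = FALSE)
  structure(list(data = data, wavelengths_nm = wavelengths_nm, kind = kind),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d rows x %d cols x %d bands (%s), %.1f-%.1f nm\n",
              d[1], d[2], d[3], x$kind,
              min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

is_hypercube <- function(x) inherits(x, "hypercube")

stopifnot_cube <- function(cube) {
  if (!is_hypercube(cube)) stop("expected a `hypercube` object", call. = FALSE)
  invisible(cube)
}

#' Validate a binary mask against a cube or image
#'
#' A binary mask is a logical matrix with the same spatial shape `[y, x]`
#' as the cube or scalar image it was derived from.
#'
#' @param mask logical matrix.
#' @param ref optional `hypercube` or matrix whose spatial shape the mask
#'   must match.
#' @return `mask`, invisibly; errors if invalid.
#' @export
validate_mask <- function(mask, ref = NULL) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  if (any(dim(mask) < 1L)) stop("mask dimensions must be >= 1", call. = FALSE)
  if (!is.null(ref)) {
    rd <- if (is_hypercube(ref)) dim(ref$data)[1:2] else dim(ref)[1:2]
    if (!identical(dim(mask), as.integer(rd)))
      stop("mask shape does not match its source image", call. = FALSE)
  }
  invisible(mask)
}

## ---- ENVI-style raster I/O -------------------------------------------------

## ENVI numeric data-type codes supported here (no BIP, no compression).
.envi_types <- list(
  `1`  = list(what = "integer", size = 1L, signed = FALSE),
  `2`  = list(what = "integer", size = 2L, signed = TRUE),
  `4`  = list(what = "double",  size = 4L, signed = TRUE),
  `5`  = list(what = "double",  size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

envi_header_path <- function(path) {
  cand <- c(paste0(tools::file_path_sans_ext(path), ".hdr"), paste0(path, ".hdr"))
  hit <- cand[file.exists(cand)]
  if (length(hit) == 0L)
    stop(sprintf("no ENVI header found for '%s' (tried %s)",
                 path, paste(cand, collapse = ", ")), call. = FALSE)
  hit[[1L]]
}

## Parse an ENVI text header into a named list of strings; `{...}` values
## may span lines. Unknown keys are kept so round-trips preserve them.
parse_envi_header <- function(hdr_path) {
  txt <- readLines(hdr_path, warn = FALSE)
  if (length(txt) == 0L || !grepl("^\\s*ENVI\\s*$", txt[[1L]]))
    stop(sprintf("'%s' is not an ENVI header (missing ENVI magic line)", hdr_path),
         call. = FALSE)
  body <- paste(txt[-1L], collapse = "\n")
  keys <- list(); pos <- 1L
  ## split on `key = value` where value runs to end of line, or `{...}` blocks
  rx <- gregexpr("(?m)^\\s*([^=\\n]+?)\\s*=\\s*(\\{[^}]*\\}|[^\\n]*)", body, perl = TRUE)[[1L]]
  if (rx[1L] == -1L) return(keys)
  starts <- attr(rx, "capture.start"); lens <- attr(rx, "capture.length")
  for (i in seq_along(rx)) {
    key <- substr(body, starts[i, 1], starts[i, 1] + lens[i, 1] - 1L)
    val <- substr(body, starts[i, 2], starts[i, 2] + lens[i, 2] - 1L)
    keys[[tolower(trimws(key))]] <- trimws(val)
  }
  keys
}

envi_num <- function(hdr, key, path) {
  v <- hdr[[key]]
  if (is.null(v)) stop(sprintf("ENVI header '%s' is missing required field '%s'",
                               path, key), call. = FALSE)
  n <- suppressWarnings(as.numeric(v))
  if (is.na(n)) stop(sprintf("ENVI header field '%s' is not numeric: '%s'", key, v),
                     call. = FALSE)
  n
}

envi_list <- function(hdr, key) {
  v <- hdr[[key]]
  if (is.null(v)) return(NULL)
  v <- gsub("[{}]", "", v)
  as.numeric(strsplit(v, "[,\\s]+", perl = TRUE)[[1L]][nzchar(strsplit(v, "[,\\s]+", perl = TRUE)[[1L]])])
}

#' Read a hyperspectral cube from an ENVI-style raster
#'
#' Supports BIL and BSQ interleaves and data types 1 (uint8), 2 (int16),
#' 4 (float32), 5 (float64) and 12 (uint16), native byte order. The text
#' header is looked for next to `path` (same basename with `.hdr`, or
#' `path` plus `.hdr`). A `data kind` header key, written by
#' [write_cube()], restores the cube's `kind` tag.
#'
#' @param path path to the binary data file (`.bil`/`.bsq`).
#' @return A [hypercube()].
#' @export
read_cube <- function(path) {
  hdr_path <- envi_header_path(path)
  hdr <- parse_envi_header(hdr_path)
  ns <- as.integer(envi_num(hdr, "samples", hdr_path))
  nl <- as.integer(envi_num(hdr, "lines", hdr_path))
  nb <- as.integer(envi_num(hdr, "bands", hdr_path))
  dtype <- as.character(as.integer(envi_num(hdr, "data type", hdr_path)))
  interleave <- tolower(hdr[["interleave"]] %||% stop(sprintf(
    "ENVI header '%s' is missing required field 'interleave'", hdr_path), call. = FALSE))
  if (!interleave %in% c("bil", "bsq"))
    stop(sprintf("unsupported interleave '%s' (only bil/bsq)", interleave), call. = FALSE)
  spec <- .envi_types[[dtype]]
  if (is.null(spec))
    stop(sprintf("unsupported ENVI data type %s", dtype), call. = FALSE)
  wl <- envi_list(hdr, "wavelength")
  if (is.null(wl))
    stop(sprintf("ENVI header '%s' is missing required field 'wavelength'", hdr_path),
         call. = FALSE)
  if (length(wl) != nb)
    stop(sprintf("wavelength count (%d) does not match band count (%d) in '%s'",
                 length(wl), nb, hdr_path), call. = FALSE)
  n <- ns * nl * nb
  con <- file(path, "rb"); on.exit(close(con))
  raw_v <- readBin(con, what = spec$what, n = n, size = spec$size,
                   signed = spec$signed, endian = "little")
  if (length(raw_v) != n)
    stop(sprintf("'%s' holds %d values but header implies %d", path, length(raw_v), n),
         call. = FALSE)
  arr <- switch(interleave,
    bsq = aperm(array(raw_v, dim = c(ns, nl, nb)), c(2L, 1L, 3L)),
    bil = aperm(array(raw_v, dim = c(ns, nb, nl)), c(3L, 1L, 2L)))
  kind <- hdr[["data kind"]] %||% "raw"
  if (!kind %in% c("raw", "dark_corrected", "reflectance")) kind <- "raw"
  hypercube(arr, wl, kind = kind)
}

#' Write a hyperspectral cube as an ENVI-style raster
#'
#' Writes the binary data file at `path` and its text header next to it.
#' The cube's `kind` tag is stored in a `data kind` header key so that
#' `read_cube(write_cube(...))` round-trips it. Integer arrays are stored
#' as int16 when they fit, otherwise as float64; numeric arrays as the
#' requested float width.
#'
#' @param cube a [hypercube()].
#' @param path output data file path; the header goes to the same basename
#'   with extension `.hdr`.
#' @param interleave `"bsq"` (default) or `"bil"`.
#' @param data_type ENVI type code 4 (float32) or 5 (float64, default) for
#'   numeric data; integer cubes within int16 range use 2 automatically.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, interleave = c("bsq", "bil"), data_type = 5L) {
  stopifnot_cube(cube)
  interleave <- match.arg(interleave)
  d <- dim(cube$data)
  vals <- cube$data
  if (is.integer(vals) && all(abs(range(vals)) <= 32767L)) {
    data_type <- 2L
  } else if (!data_type %in% c(4L, 5L)) {
    stop("data_type must be 4 (float32) or 5 (float64)", call. = FALSE)
  }
  arr <- switch(interleave,
    bsq = aperm(vals, c(2L, 1L, 3L)),
    bil = aperm(vals, c(2L, 3L, 1L)))
  spec <- .envi_types[[as.character(data_type)]]
  con <- file(path, "wb")
  writeBin(as.vector(arr, mode = spec$what), con, size = spec$size, endian = "little")
  close(con)
  hdr_path <- paste0(tools::file_path_sans_ext(path), ".hdr")
  wl <- paste(format(cube$wavelengths_nm, trim = TRUE, scientific = FALSE, digits = 12),
              collapse = ", ")
  writeLines(c(
    "ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("data kind = %s", cube$kind),
    sprintf("wavelength = { %s }", wl)), hdr_path)
  invisible(path)
}

#' Read and write binary masks as 8-bit PNG
#'
#' Masks are stored as single-channel 8-bit images with `TRUE` mapped to
#' 255 and `FALSE` to 0; the round-trip is lossless.
#'
#' @param mask logical matrix.
#' @param path PNG file path.
#' @return `write_mask` returns `path` invisibly; `read_mask` returns a
#'   logical matrix.
#' @export
write_mask <- function(mask, path) {
  validate_mask(mask)
  png::writePNG(ifelse(mask, 1, 0), target = path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > 0.5
}

`%||%` <- function(a, b) if (is.null(a)) b else a
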