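## Classed condition for detection failures, so callers can tell a method
## failure (no tile found, everything occluded) from an I/O or config error.
detection_error <- function(msg) {
  stop(structure(class = c("hyperrow_detection_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its default. Values can be
#' overridden from a flat YAML file ([load_pipeline_config()]) or
#' programmatically; unknown keys are rejected by name.
#'
#' \describe{
#'   \item{ndvi_threshold (0.3)}{fixed NDVI cut for VNIR plant pixels.}
#'   \item{swir_bottom_crop_fraction (0.15)}{bottom rows cleared from SWIR
#'     masks.}
#'   \item{lambda_ver (0.05)}{vertical move penalty of every seam; small
#'     enough that a unit gradient edge (cost drop of 1) always dominates
#'     a one-pixel vertical move.}
#'   \item{lambda_dist (0.01)}{weight of the tile-width distance penalty.}
#'   \item{expected_tile_width_px (40)}{expected white-reference width.}
#'   \item{whiteref_dark_fraction (0.8)}{darkness cut for occluded
#'     columns, relative to the median valid-column mean.}
#'   \item{section_width_px (100)}{normalisation section width.}
#'   \item{n_plants (12)}{known plants per row image.}
#'   \item{expected_spacing_px (NULL)}{plant pitch; width / n_plants when
#'     unset.}
#'   \item{crop_start, crop_end (NULL)}{row-end crop columns (0-based,
#'     half-open); no crop when unset.}
#'   \item{swath_m (1.2), vnir_swath_px (402), swir_swath_px (378)}{height
#'     calibration.}
#' }
#'
#' @return Named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(ndvi_threshold = 0.3,
       swir_bottom_crop_fraction = 0.15,
       lambda_ver = 0.05,
       lambda_dist = 0.01,
       expected_tile_width_px = 40,
       whiteref_dark_fraction = 0.8,
       section_width_px = 100,
       n_plants = 12L,
       expected_spacing_px = NULL,
       crop_start = NULL,
       crop_end = NULL,
       swath_m = 1.2,
       vnir_swath_px = 402L,
       swir_swath_px = 378L)
}

validate_pipeline_config <- function(cfg) {
  if (cfg$n_plants < 1L) stop("config error: n_plants must be >= 1", call. = FALSE)
  if (cfg$ndvi_threshold <= -1 || cfg$ndvi_threshold >= 1)
    stop("config error: ndvi_threshold must lie in (-1, 1)", call. = FALSE)
  if (cfg$swir_bottom_crop_fraction < 0 || cfg$swir_bottom_crop_fraction >= 1)
    stop("config error: swir_bottom_crop_fraction must lie in [0, 1)", call. = FALSE)
  if (cfg$lambda_ver < 0 || cfg$lambda_dist < 0)
    stop("config error: lambda_ver and lambda_dist must be >= 0", call. = FALSE)
  if (cfg$expected_tile_width_px < 1)
    stop("config error: expected_tile_width_px must be >= 1", call. = FALSE)
  if (cfg$section_width_px < 1)
    stop("config error: section_width_px must be >= 1", call. = FALSE)
  cfg
}

#' Load a pipeline configuration file
#'
#' Flat key-value YAML; keys not present in
#' [default_pipeline_config()] are rejected with the offending name.
#' Overrides passed as `...` take precedence over the file, which takes
#' precedence over the defaults.
#'
#' @param path YAML file path, or `NULL` for defaults only.
#' @param ... named overrides.
#' @return Validated configuration list.
#' @export
load_pipeline_config <- function(path = NULL, ...) {
  cfg <- default_pipeline_config()
  apply_over <- function(cfg, over, origin) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) > 0L)
      stop(sprintf("config error: unknown key '%s' (%s)", unknown[1L], origin),
           call. = FALSE)
    cfg[names(over)] <- over
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file '%s' not found", path), call. = FALSE)
    cfg <- apply_over(cfg, yaml::read_yaml(path), path)
  }
  over <- list(...)
  if (length(over) > 0L) cfg <- apply_over(cfg, over, "override")
  validate_pipeline_config(cfg)
}

write_spectra_csv <- function(spectra, wavelengths, path) {
  df <- as.data.frame(spectra)
  names(df) <- sprintf("wl_%.1f", wavelengths)
  df <- cbind(plant_id = seq_len(nrow(spectra)), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

process_scanner <- function(cube, scanner, cfg, log) {
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e) {
      kind <- if (inherits(e, "hyperrow_detection_error")) "detection failure" else "error"
      stop(sprintf("[%s/%s] %s: %s", scanner, name, kind, conditionMessage(e)),
           call. = FALSE)
    })
    log(sprintf("[%s] %s done in %.2fs", scanner, name, proc.time()[["elapsed"]] - t0))
    r
  }
  seg <- stage("segment", {
    if (scanner == "vnir") {
      detect_plants_vnir(cube, segmentation_params(cfg$ndvi_threshold,
                                                   cfg$swir_bottom_crop_fraction),
                         cfg$lambda_ver)
    } else {
      detect_plants_swir(cube, segmentation_params(cfg$ndvi_threshold,
                                                   cfg$swir_bottom_crop_fraction))
    }
  })
  panel <- stage("whiteref", {
    if (scanner == "vnir") {
      detect_whiteref_vnir(cube, cfg$expected_tile_width_px, cfg$lambda_ver,
                           cfg$lambda_dist)
    } else {
      detect_whiteref_swir(cube)
    }
  })
  refl <- stage("normalize", normalize_reflectance(cube, panel, cfg$section_width_px))
  regions <- stage("split", {
    split_row(column_profile(seg$mask), cfg$n_plants, cfg$expected_spacing_px)
  })
  swath_px <- if (scanner == "vnir") cfg$vnir_swath_px else cfg$swir_swath_px
  extracted <- stage("extract", {
    extract_plant_data(refl, seg$mask, regions, cfg$swath_m, swath_px)
  })
  list(mask = seg$mask, panel = panel, refl = refl, regions = regions,
       traits = extracted$traits, spectra = extracted$spectra)
}

#' Run the full per-row pipeline
#'
#' Preprocess, segment, detect the white reference, normalise to
#' reflectance, split into plants, and extract traits for one row image
#' from each scanner (the two scanners are processed independently; the
#' images are not registered). Writes per-scanner plant and tile masks
#' (PNG), regions/traits/spectra CSVs, reflectance cubes (ENVI) and a
#' JSON manifest holding every effective parameter, per-stage timings and
#' warnings, which alone suffices to reproduce the run.
#'
#' @param vnir_path,swir_path ENVI data files; either may be `NULL` to
#'   skip that scanner.
#' @param cfg configuration from [load_pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param dark_path optional SWIR dark-current spectrum file
#'   ([read_dark_spectrum()]).
#' @param verbose log stage progress to stderr.
#' @return `out_dir`, invisibly; see the manifest for the file inventory.
#' @export
run_row <- function(vnir_path = NULL, swir_path = NULL,
                    cfg = default_pipeline_config(), out_dir,
                    dark_path = NULL, verbose = FALSE) {
  cfg <- validate_pipeline_config(cfg)
  if (is.null(vnir_path) && is.null(swir_path))
    stop("at least one of vnir_path/swir_path is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(msg) if (verbose) message(msg)
  warnings_seen <- character(0)
  results <- list()
  t_start <- proc.time()[["elapsed"]]

  load_one <- function(path, scanner) {
    cube <- tryCatch(read_cube(path), error = function(e)
      stop(sprintf("[%s/read] I/O error: %s", scanner, conditionMessage(e)),
           call. = FALSE))
    if (!is.null(cfg$crop_start) && !is.null(cfg$crop_end))
      cube <- crop_row_ends(cube, cfg$crop_start, cfg$crop_end)
    cube
  }

  for (scanner in c("vnir", "swir")) {
    path <- if (scanner == "vnir") vnir_path else swir_path
    if (is.null(path)) next
    cube <- load_one(path, scanner)
    if (scanner == "swir" && !is.null(dark_path))
      cube <- subtract_dark_current(cube, read_dark_spectrum(dark_path))
    res <- withCallingHandlers(
      process_scanner(cube, scanner, cfg, log),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    prefix <- file.path(out_dir, scanner)
    write_mask(res$mask, paste0(prefix, "_plant_mask.png"))
    write_mask(res$panel$mask, paste0(prefix, "_whiteref_mask.png"))
    utils::write.csv(res$regions, paste0(prefix, "_regions.csv"), row.names = FALSE)
    utils::write.csv(res$traits, paste0(prefix, "_traits.csv"), row.names = FALSE)
    write_spectra_csv(res$spectra, cube$wavelengths_nm, paste0(prefix, "_spectra.csv"))
    write_cube(res$refl, paste0(prefix, "_reflectance.bsq"))
    utils::write.csv(
      data.frame(column = seq_along(res$panel$column_valid) - 1L,
                 valid = res$panel$column_valid),
      paste0(prefix, "_whiteref_columns.csv"), row.names = FALSE)
    results[[scanner]] <- list(
      n_regions = nrow(res$regions),
      n_plant_pixels = sum(res$mask),
      n_valid_whiteref_columns = sum(res$panel$column_valid),
      plants_with_pixels = sum(res$traits$n_pixels > 0L))
  }

  manifest <- list(
    package = "hyperrow",
    version = as.character(utils::packageVersion("hyperrow")),
    r_version = R.version.string,
    inputs = list(vnir = vnir_path, swir = swir_path, dark = dark_path),
    config = cfg[!vapply(cfg, is.null, logical(1))],
    results = results,
    warnings = warnings_seen,
    elapsed_s = proc.time()[["elapsed"]] - t_start)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
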