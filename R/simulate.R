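## Label codes used in rendered scene label maps.
.scene_labels <- c(cardboard = 1L, grass = 2L, tile = 3L, post = 4L, plant = 5L)

#' Default scene endmember reflectance spectra
#'
#' Five hand-built piecewise-linear reflectance curves evaluated on the
#' requested wavelength grids: `leaf` (red absorption, red edge, NIR
#' plateau, SWIR water absorption with 1411 nm depressed relative to
#' 1375 nm), `grass` (a slightly dimmer leaf), `cardboard` (spectrally
#' flat, gently rising), `tile` (the white reference: flat and highest
#' everywhere, with a mild dip at 1620 nm that makes it the low mode of
#' the 1620/1537 index) and `post` (dark wood). They carry enough spectral
#' structure for every index the pipeline uses; they are synthetic shapes,
#' not measured spectra.
#'
#' @param vnir_wl,swir_wl wavelength grids in nm.
#' @return List with `vnir` and `swir`, each a `5 x bands` matrix with
#'   rows named cardboard, grass, tile, post, leaf.
#' @export
default_endmembers <- function(vnir_wl = seq(400, 896, length.out = 178),
                               swir_wl = seq(895, 2506, length.out = 278)) {
  pts <- list(
    leaf = list(
      x = c(400, 500, 550, 620, 650, 680, 700, 710, 740, 780, 896,
            1100, 1300, 1375, 1411, 1450, 1500, 1537, 1620, 1680, 1750,
            1900, 1940, 2100, 2200, 2350, 2506),
      y = c(0.05, 0.06, 0.12, 0.07, 0.04, 0.04, 0.15, 0.30, 0.48, 0.50, 0.48,
            0.45, 0.41, 0.38, 0.28, 0.12, 0.16, 0.20, 0.26, 0.28, 0.26,
            0.07, 0.05, 0.15, 0.18, 0.12, 0.08)),
    grass = list(
      x = c(400, 500, 550, 620, 650, 680, 700, 710, 740, 780, 896,
            1100, 1300, 1375, 1411, 1450, 1500, 1537, 1620, 1680, 1750,
            1900, 1940, 2100, 2200, 2350, 2506),
      y = c(0.06, 0.07, 0.11, 0.07, 0.05, 0.05, 0.14, 0.26, 0.42, 0.44, 0.42,
            0.40, 0.37, 0.34, 0.25, 0.11, 0.15, 0.18, 0.24, 0.25, 0.23,
            0.07, 0.05, 0.13, 0.16, 0.11, 0.07)),
    cardboard = list(
      x = c(400, 896, 1500, 2506),
      y = c(0.22, 0.28, 0.29, 0.34)),
    tile = list(
      x = c(400, 896, 1500, 1537, 1620, 1700, 2506),
      y = c(0.95, 0.95, 0.95, 0.94, 0.85, 0.88, 0.84)),
    post = list(
      x = c(400, 896, 2506),
      y = c(0.08, 0.10, 0.11)))
  eval_grid <- function(wl) {
    m <- t(vapply(pts[c("cardboard", "grass", "tile", "post", "leaf")],
                  function(p) stats::approx(p$x, p$y, xout = wl, rule = 2)$y,
                  numeric(length(wl))))
    rownames(m) <- c("cardboard", "grass", "tile", "post", "leaf")
    m
  }
  list(vnir = eval_grid(vnir_wl), swir = eval_grid(swir_wl))
}

#' Synthetic row-scene configuration
#'
#' Geometry and signal parameters of a simulated lateral-view scene of one
#' crop row: a cardboard sheet fills the background, a grass strip runs
#' along the bottom, a horizontal white-reference tile strip is attached
#' to the cardboard, vertical wooden posts occlude it in places, and the
#' plants are rendered as unions of overlapping ellipses standing just
#' above the grass. The scanner defaults match the field set-up the
#' package was built around: a VNIR scanner with 178 bands over
#' 400-896 nm and 402 vertical pixels spanning a 1.2 m swath, and a SWIR
#' scanner with 278 bands over 895-2506 nm and 378 vertical pixels. All
#' vertical geometry is specified as fractions of image height so the two
#' scanners see the same scene.
#'
#' @param n_plants plants in the row (the trial this emulates used 48 per
#'   row; the short example rows hold 12).
#' @param spacing_px horizontal pixels per plant pitch.
#' @param vnir_height,vnir_bands,swir_height,swir_bands scanner geometry.
#' @param plant_height_frac,plant_width_frac ranges (fractions of image
#'   height / plant pitch) that plant sizes are drawn from.
#' @param plant_base_frac vertical fraction where plants stand.
#' @param missing_plants indices of plants forced absent (zero size).
#' @param missing_prob probability that any other plant is absent.
#' @param tile_top_frac,tile_height_frac vertical placement of the tile
#'   strip (must end above the grass strip).
#' @param grass_frac height fraction of the bottom grass strip.
#' @param n_posts,post_width_px occluding posts.
#' @param illum_amplitude relative peak-to-peak amplitude of the smooth
#'   column-wise illumination drift (0 = constant light).
#' @param noise_sd additive Gaussian sensor noise, in digital numbers.
#' @param dark_amplitude_swir mean SWIR dark current in digital numbers
#'   (VNIR dark current is negligible and not simulated).
#' @param gain digital numbers per unit reflectance at nominal light.
#' @param seed RNG seed; scenes are bit-reproducible given the seed.
#' @return A `scene_config` list.
#' @export
scene_config <- function(n_plants = 12L, spacing_px = 40L,
                         vnir_height = 402L, vnir_bands = 178L,
                         swir_height = 378L, swir_bands = 278L,
                         plant_height_frac = c(0.35, 0.55),
                         plant_width_frac = c(0.60, 0.85),
                         plant_base_frac = 0.83,
                         missing_plants = integer(0),
                         missing_prob = 0,
                         tile_top_frac = 0.10, tile_height_frac = 0.10,
                         grass_frac = 0.14,
                         n_posts = 2L, post_width_px = 4L,
                         illum_amplitude = 0.2,
                         noise_sd = 5,
                         dark_amplitude_swir = 40,
                         gain = 1000,
                         seed = 1L) {
  cfg <- list(n_plants = as.integer(n_plants), spacing_px = as.integer(spacing_px),
              vnir_height = as.integer(vnir_height), vnir_bands = as.integer(vnir_bands),
              swir_height = as.integer(swir_height), swir_bands = as.integer(swir_bands),
              plant_height_frac = plant_height_frac,
              plant_width_frac = plant_width_frac,
              plant_base_frac = plant_base_frac,
              missing_plants = as.integer(missing_plants),
              missing_prob = missing_prob,
              tile_top_frac = tile_top_frac, tile_height_frac = tile_height_frac,
              grass_frac = grass_frac,
              n_posts = as.integer(n_posts), post_width_px = as.integer(post_width_px),
              illum_amplitude = illum_amplitude, noise_sd = noise_sd,
              dark_amplitude_swir = dark_amplitude_swir, gain = gain,
              seed = as.integer(seed))
  if (cfg$n_plants < 1L || cfg$spacing_px < 4L)
    stop("need n_plants >= 1 and spacing_px >= 4", call. = FALSE)
  if (any(c(cfg$vnir_height, cfg$vnir_bands, cfg$swir_height, cfg$swir_bands) < 8L))
    stop("scanner dimensions must be >= 8", call. = FALSE)
  if (cfg$missing_prob < 0 || cfg$missing_prob > 1)
    stop("`missing_prob` must lie in [0, 1]", call. = FALSE)
  if (cfg$tile_top_frac + cfg$tile_height_frac >= 1 - cfg$grass_frac)
    stop("tile strip overlaps the grass strip", call. = FALSE)
  if (cfg$illum_amplitude < 0 || cfg$illum_amplitude >= 2)
    stop("`illum_amplitude` must lie in [0, 2)", call. = FALSE)
  structure(cfg, class = "scene_config")
}

## Render the label map for one scanner height from fractional geometry.
render_label_map <- function(height, width, cfg, plants) {
  lbl <- matrix(.scene_labels[["cardboard"]], height, width)
  grass_row0 <- floor(height * (1 - cfg$grass_frac)) + 1L
  lbl[grass_row0:height, ] <- .scene_labels[["grass"]]
  tile_rows <- (floor(height * cfg$tile_top_frac) + 1L):
               floor(height * (cfg$tile_top_frac + cfg$tile_height_frac))
  lbl[tile_rows, ] <- .scene_labels[["tile"]]
  post_top <- max(1L, floor(height * 0.04) + 1L)
  for (px in plants$post_x0) {
    cols <- (px + 1L):min(px + cfg$post_width_px, width)
    lbl[post_top:(grass_row0 - 1L), cols] <- .scene_labels[["post"]]
  }
  base_row <- height * cfg$plant_base_frac
  for (i in seq_len(nrow(plants$table))) {
    p <- plants$table[i, ]
    if (p$missing) next
    for (k in seq_len(ncol(plants$blob_dx))) {
      h_px <- p$height_frac * height
      cy <- base_row - h_px / 2 + plants$blob_dy[i, k] * h_px
      cx <- p$centre_x + plants$blob_dx[i, k] * p$width_px
      ay <- h_px / 2 * plants$blob_sy[i, k]
      ax <- p$width_px / 2 * plants$blob_sx[i, k]
      y_rng <- max(1L, floor(cy - ay)):min(floor(base_row), ceiling(cy + ay))
      x_rng <- max(1L, floor(cx - ax + 1)):min(width, ceiling(cx + ax + 1))
      if (length(y_rng) == 0L || length(x_rng) == 0L) next
      inside <- outer(((y_rng - cy) / ay)^2, (((x_rng - 0.5) - cx) / ax)^2, `+`) <= 1
      sub <- lbl[y_rng, x_rng, drop = FALSE]
      sub[inside] <- .scene_labels[["plant"]]
      lbl[y_rng, x_rng] <- sub
    }
  }
  list(labels = lbl, grass_row0 = grass_row0, tile_rows = tile_rows)
}

render_cube <- function(labels, E, wl, illum, dark, noise_sd, gain) {
  storage.mode(labels) <- "integer"
  arr <- render_cube_native(labels, E, illum, dark, noise_sd, gain,
                            has_dark = any(dark != 0))
  hypercube(arr, wl, kind = "raw")
}

#' Generate a synthetic row scene with ground truth
#'
#' Renders seeded VNIR and SWIR cubes of the same simulated scene plus the
#' full ground truth every pipeline test needs: per-material masks for
#' each scanner, the cardboard-bottom boundary row per column, per-plant
#' centre columns and spans, the endmember spectra, and the injected
#' illumination and dark-current fields. Pixel intensities are
#' `reflectance x illumination x gain + dark + Gaussian noise`; the same
#' smooth illumination drift multiplies every scene element, which is
#' exactly what the sectioned white-reference normalisation must cancel.
#'
#' @param cfg a [scene_config()].
#' @return List with `vnir`, `swir` ([hypercube()]s) and `truth` (see
#'   details), plus the `config`.
#' @export
generate_scene <- function(cfg = scene_config()) {
  if (!inherits(cfg, "scene_config")) stop("expected a `scene_config`", call. = FALSE)
  set.seed(cfg$seed)
  width <- cfg$n_plants * cfg$spacing_px
  vnir_wl <- seq(400, 896, length.out = cfg$vnir_bands)
  swir_wl <- seq(895, 2506, length.out = cfg$swir_bands)
  em <- default_endmembers(vnir_wl, swir_wl)

  ## per-plant geometry (in fractions / pixels of the shared x axis)
  n <- cfg$n_plants
  missing <- seq_len(n) %in% cfg$missing_plants |
    stats::runif(n) < cfg$missing_prob
  tab <- data.frame(
    plant_id = seq_len(n),
    centre_x = (seq_len(n) - 0.5) * cfg$spacing_px +
      stats::runif(n, -0.05, 0.05) * cfg$spacing_px,
    span_start = (seq_len(n) - 1L) * cfg$spacing_px,
    span_end = seq_len(n) * cfg$spacing_px,
    height_frac = stats::runif(n, cfg$plant_height_frac[1], cfg$plant_height_frac[2]),
    width_px = stats::runif(n, cfg$plant_width_frac[1], cfg$plant_width_frac[2]) *
      cfg$spacing_px,
    missing = missing)
  n_blob <- 4L
  plants <- list(
    table = tab,
    blob_dx = matrix(stats::runif(n * n_blob, -0.12, 0.12), n, n_blob),
    blob_dy = matrix(stats::runif(n * n_blob, -0.15, 0.15), n, n_blob),
    blob_sx = matrix(stats::runif(n * n_blob, 0.75, 1.0), n, n_blob),
    blob_sy = matrix(stats::runif(n * n_blob, 0.75, 1.0), n, n_blob),
    post_x0 = if (cfg$n_posts > 0L)
      sort(sample.int(max(1L, width - cfg$post_width_px), cfg$n_posts))
      else integer(0))
  plants$blob_dx[, 1L] <- 0; plants$blob_dy[, 1L] <- 0
  plants$blob_sx[, 1L] <- 1; plants$blob_sy[, 1L] <- 1

  ## smooth low-order polynomial illumination drift, shared by all elements
  xs <- seq(-1, 1, length.out = width)
  coef <- stats::runif(3, -1, 1)
  p <- coef[1] * xs + coef[2] * xs^2 + coef[3] * xs^3
  if (diff(range(p)) > 0) {
    p <- (p - min(p)) / diff(range(p))   # [0, 1]
  } else p <- rep(0.5, width)
  illum <- 1 - cfg$illum_amplitude / 2 + cfg$illum_amplitude * p

  dark_phase <- stats::runif(1, 0, 2 * pi)
  mk_dark <- function(h, nb, amp) {
    if (amp <= 0) return(matrix(0, h, nb))
    rowf <- amp * (0.75 + 0.25 * sin(2 * pi * seq_len(h) / h + dark_phase))
    bandf <- 0.8 + 0.4 * seq(0, 1, length.out = nb)
    outer(rowf, bandf)
  }
  dark_vnir <- mk_dark(cfg$vnir_height, cfg$vnir_bands, 0)
  dark_swir <- mk_dark(cfg$swir_height, cfg$swir_bands, cfg$dark_amplitude_swir)

  scene_truth <- function(height, E, wl, dark) {
    r <- render_label_map(height, width, cfg, plants)
    list(labels = r$labels,
         plant_mask = r$labels == .scene_labels[["plant"]],
         tile_mask = r$labels == .scene_labels[["tile"]],
         grass_mask = r$labels == .scene_labels[["grass"]],
         post_mask = r$labels == .scene_labels[["post"]],
         boundary_row = rep.int(r$grass_row0 - 1L, width),
         tile_rows = r$tile_rows)
  }
  tv <- scene_truth(cfg$vnir_height, em$vnir, vnir_wl, dark_vnir)
  ts <- scene_truth(cfg$swir_height, em$swir, swir_wl, dark_swir)

  vnir <- render_cube(tv$labels, em$vnir, vnir_wl, illum, dark_vnir,
                      cfg$noise_sd, cfg$gain)
  swir <- render_cube(ts$labels, em$swir, swir_wl, illum, dark_swir,
                      cfg$noise_sd, cfg$gain)

  truth <- list(vnir = tv, swir = ts,
                plants = tab,
                post_x0 = plants$post_x0,
                endmembers = em,
                wavelengths = list(vnir = vnir_wl, swir = swir_wl),
                illumination = illum,
                dark = list(vnir = dark_vnir, swir = dark_swir))
  list(vnir = vnir, swir = swir, truth = truth, config = cfg)
}
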