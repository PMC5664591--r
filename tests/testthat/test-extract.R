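region_row <- function(fs, fe, as = NULL, ae = NULL, id = 1L) {
  data.frame(plant_id = id, full_start = fs, full_end = fe,
             analysis_start = if (is.null(as)) fs else as,
             analysis_end = if (is.null(ae)) fe else ae)
}

test_that("a cube equal to the tile spectrum normalises to reflectance 1", {
  set.seed(23)
  tile_spec <- runif(4, 500, 900)
  arr <- array(rep(tile_spec, each = 6 * 10), c(6, 10, 4))
  cube <- hypercube(arr, c(1000, 1100, 1200, 1300))
  mask <- matrix(FALSE, 6, 10); mask[2:3, ] <- TRUE
  panel <- whiteref_panel(mask, cube)
  refl <- normalize_reflectance(cube, panel, section_width_px = 4)
  expect_equal(refl$data, array(1, dim(arr)))
  expect_identical(refl$kind, "reflectance")
})

test_that("a per-section illumination scale cancels in sectioned normalisation", {
  set.seed(24)
  base <- runif(3, 0.2, 0.9)          # scene reflectance spectrum
  tile <- rep(1, 3)
  arr <- array(0, c(4, 8, 3))
  scale_x <- rep(c(1, 2), each = 4)   # section 2 lit twice as bright
  for (x in 1:8) {
    arr[1, x, ] <- tile * scale_x[x]  # tile row
    for (y in 2:4) arr[y, x, ] <- base * scale_x[x]
  }
  cube <- hypercube(arr, c(1000, 1100, 1200))
  mask <- matrix(FALSE, 4, 8); mask[1, ] <- TRUE
  refl <- normalize_reflectance(cube, whiteref_panel(mask, cube), section_width_px = 4)
  for (y in 2:4) for (x in 1:8) expect_equal(refl$data[y, x, ], base)
})

test_that("sections without valid reference columns borrow the nearest section", {
  arr <- array(2, c(3, 9, 2))
  cube <- hypercube(arr, c(1000, 1100))
  mask <- matrix(FALSE, 3, 9); mask[1, 1:3] <- TRUE   # only section 1 has tile
  refl <- normalize_reflectance(cube, whiteref_panel(mask, cube), section_width_px = 3)
  expect_equal(refl$data, array(1, c(3, 9, 2)))
})

test_that("normalisation errors are specific", {
  arr <- array(1, c(3, 4, 2)); arr[1, , 2] <- 0
  cube <- hypercube(arr, c(1000, 1100))
  mask <- matrix(FALSE, 3, 4); mask[1, ] <- TRUE
  panel <- whiteref_panel(mask, cube)
  expect_error(normalize_reflectance(cube, panel), "band 2")

  panel$column_valid[] <- FALSE
  expect_error(normalize_reflectance(cube, panel), "no valid columns")
})

test_that("plant height reflects the mask's vertical extent and swath calibration", {
  mask <- matrix(FALSE, 402, 20)
  reg <- region_row(0L, 20L)
  expect_equal(plant_height(mask, reg)$height_px, 0L)

  mask[100, 5] <- TRUE
  expect_equal(plant_height(mask, reg)$height_px, 1L)

  mask[, 5] <- TRUE
  h <- plant_height(mask, reg, swath_m = 1.2, swath_px = 402L)
  expect_equal(h$height_px, 402L)
  expect_equal(h$height_m, 1.2)
})

test_that("height and density are invariant to whole-column translation", {
  set.seed(25)
  m <- matrix(runif(30 * 40) > 0.7, 30, 40)
  shifted <- cbind(matrix(FALSE, 30, 7), m)
  r1 <- region_row(4L, 30L)
  r2 <- region_row(11L, 37L)
  expect_equal(plant_height(m, r1), plant_height(shifted, r2))
  expect_equal(plant_density(m, r1), plant_density(shifted, r2))
})

test_that("plant density is plant pixels per analysis column", {
  mask <- matrix(FALSE, 10, 12)
  reg <- region_row(2L, 8L)
  expect_equal(plant_density(mask, reg), 0)
  mask[] <- TRUE
  expect_equal(plant_density(mask, reg), 10)
  set.seed(26)
  mask <- matrix(runif(120) > 0.5, 10, 12)
  brute <- sum(mask[, 3:8]) / 6
  expect_equal(plant_density(mask, reg), brute)
})

test_that("plant mean spectra average the masked pixels only", {
  set.seed(27)
  arr <- array(runif(5 * 6 * 3), c(5, 6, 3))
  cube <- hypercube(arr, c(1000, 1100, 1200), kind = "reflectance")
  reg <- region_row(0L, 6L)

  one <- matrix(FALSE, 5, 6); one[3, 4] <- TRUE
  expect_equal(plant_mean_spectrum(cube, one, reg), arr[3, 4, ])

  uni <- hypercube(array(0.42, c(5, 6, 3)), c(1000, 1100, 1200), kind = "reflectance")
  m <- matrix(runif(30) > 0.5, 5, 6)
  expect_equal(plant_mean_spectrum(uni, m, reg), rep(0.42, 3))

  expect_error(plant_mean_spectrum(cube, matrix(FALSE, 5, 6), reg), "no plant pixels")
})

test_that("the full extraction chain recovers the simulated leaf spectrum", {
  cfg <- tiny_cfg(seed = 28)
  sc <- generate_scene(cfg)
  det <- detect_plants_vnir(sc$vnir)
  panel <- detect_whiteref_vnir(sc$vnir,
                                expected_width = floor(cfg$tile_height_frac * cfg$vnir_height))
  refl <- normalize_reflectance(sc$vnir, panel, section_width_px = 40)
  reg <- split_row(column_profile(det$mask), cfg$n_plants, cfg$spacing_px)
  out <- extract_plant_data(refl, det$mask, reg)
  leaf <- sc$truth$endmembers$vnir["leaf", ] / sc$truth$endmembers$vnir["tile", ]
  for (i in which(out$traits$n_pixels > 100)) {
    expect_gte(stats::cor(out$spectra[i, ], leaf), 0.99)
  }
  # tile pixels sit near reflectance 1
  tile_px <- sc$truth$vnir$tile_mask & panel$mask
  means <- vapply(seq_len(dim(refl)[3]), function(b) {
    mean(refl$data[, , b][tile_px])
  }, numeric(1))
  expect_true(all(abs(means - 1) < 0.05))
})
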