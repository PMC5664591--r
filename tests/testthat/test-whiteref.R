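test_that("VNIR white-reference detection recovers the tile and flags posts", {
  cfg <- tiny_cfg(seed = 15)
  sc <- generate_scene(cfg)
  expected_w <- floor(cfg$tile_height_frac * cfg$vnir_height)
  panel <- detect_whiteref_vnir(sc$vnir, expected_width = expected_w)
  truth <- sc$truth$vnir

  covered <- sum(panel$mask & truth$tile_mask) / sum(truth$tile_mask)
  expect_gte(covered, 0.75)

  # an unoccluded tile: near-total coverage and almost no false pixels
  sc0 <- generate_scene(tiny_cfg(seed = 15, n_posts = 0L))
  panel0 <- detect_whiteref_vnir(sc0$vnir, expected_width = expected_w)
  truth0 <- sc0$truth$vnir
  expect_gte(sum(panel0$mask & truth0$tile_mask) / sum(truth0$tile_mask), 0.75)
  expect_lte(sum(panel0$mask & !truth0$tile_mask) / sum(panel0$mask), 0.02)

  # seams bracket the tile in every valid column
  top <- attr(panel, "top"); bottom <- attr(panel, "bottom")
  expect_true(all(top$y[panel$column_valid] < bottom$y[panel$column_valid]))

  # post-occluded columns are flagged invalid
  post_cols <- unlist(lapply(sc$truth$post_x0,
                             function(p) (p + 1):(p + cfg$post_width_px)))
  expect_false(any(panel$column_valid[post_cols]))
  # and the panel never intersects the plants
  expect_false(any(panel$mask & truth$plant_mask))
})

test_that("an oversized expected width is rejected", {
  sc <- generate_scene(tiny_cfg(seed = 16))
  expect_error(detect_whiteref_vnir(sc$vnir, expected_width = 500),
               "above the image")
})

test_that("occlusion filtering removes high-variance and dark columns only", {
  # synthetic panel: uniform tile of intensity 100 in rows 3..8, 30 columns
  img <- matrix(100, 12, 30)
  mask <- matrix(FALSE, 12, 30); mask[3:8, ] <- TRUE
  wl <- c(500, 600)
  cube <- hypercube(array(img, c(12, 30, 2)), wl)

  clean <- filter_occluded_columns(whiteref_panel(mask, cube), img)
  expect_true(all(clean$column_valid))

  # a half-dark column trips the variance rule
  img2 <- img; img2[3:5, 7] <- 10
  cube2 <- hypercube(array(img2, c(12, 30, 2)), wl)
  p2 <- filter_occluded_columns(whiteref_panel(mask, cube2), img2)
  expect_false(p2$column_valid[7])
  expect_true(all(p2$column_valid[-7]))
  expect_true(all(is.na(p2$spectra[7, ])))

  # a uniformly dimmed but clean tile: equal variances, no removals
  img3 <- img * 0.95
  cube3 <- hypercube(array(img3, c(12, 30, 2)), wl)
  p3 <- filter_occluded_columns(whiteref_panel(mask, cube3), img3)
  expect_true(all(p3$column_valid))

  # a uniformly dark column trips the darkness rule despite zero variance
  img4 <- img; img4[3:8, 11] <- 40
  cube4 <- hypercube(array(img4, c(12, 30, 2)), wl)
  p4 <- filter_occluded_columns(whiteref_panel(mask, cube4), img4)
  expect_false(p4$column_valid[11])
})

test_that("histogram local-minimum threshold lands between the first two modes", {
  set.seed(17)
  # three-component mixture: tile (10%), background (60%), plants (30%)
  v <- c(rnorm(1000, -0.05, 0.008), rnorm(6000, 0.01, 0.008), rnorm(3000, 0.13, 0.01))
  img <- matrix(v, 100, 100)
  thr <- histogram_local_minimum(img)
  expect_gt(thr, -0.04); expect_lt(thr, 0.005)

  # two-value image with 10% at the low value
  v2 <- c(rep(0.2, 100), rep(0.9, 900))
  img2 <- matrix(v2, 50, 20)
  thr2 <- histogram_local_minimum(img2)
  expect_gt(thr2, 0.2); expect_lt(thr2, 0.9)
  mask2 <- erode_cross(img2 < thr2)
  expect_identical(mask2, erode_cross(img2 == 0.2))

  expect_error(histogram_local_minimum(matrix(1, 4, 4)), "constant")
})

test_that("SWIR white-reference detection recovers the tile mask", {
  cfg <- tiny_cfg(seed = 18)
  sc <- generate_scene(cfg)
  panel <- detect_whiteref_swir(sc$swir)
  truth <- sc$truth$swir
  # the 8-row tiny tile loses its border rows to the cross erosion, which
  # bounds the achievable IoU near 0.72; full-scale recovery is checked on
  # default scenes elsewhere
  expect_gte(iou(panel$mask, truth$tile_mask), 0.65)
  expect_false(any(panel$mask & truth$plant_mask))
  # valid columns have at least one mask pixel by construction
  expect_true(all(colSums(panel$mask)[panel$column_valid] >= 1))
  # spectra rows align with validity
  expect_true(all(!is.na(panel$spectra[panel$column_valid, ])))
  expect_true(all(is.na(panel$spectra[!panel$column_valid, ])))
})
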