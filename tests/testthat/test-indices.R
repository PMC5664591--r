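cube_from_bands <- function(..., wl) {
  bands <- list(...)
  arr <- array(unlist(bands), c(dim(bands[[1]]), length(bands)))
  hypercube(arr, wl)
}

test_that("band_mean selects and averages bands correctly", {
  set.seed(3)
  arr <- array(runif(4 * 3 * 5), c(4, 3, 5))
  wl <- c(500, 510, 520, 530, 540)
  cube <- hypercube(arr, wl)

  expect_equal(band_mean(cube, band_range(518, 522)), arr[, , 3])
  expect_equal(band_mean(cube, band_centred(520, 1)), arr[, , 3])

  # centred 3-band window around band 3: brute-force mean of bands 2..4
  brute <- (arr[, , 2] + arr[, , 3] + arr[, , 4]) / 3
  expect_equal(band_mean(cube, band_centred(520, 3)), brute)

  # range mode is endpoint-inclusive
  expect_equal(band_mean(cube, band_range(510, 530)), brute)

  const <- hypercube(array(2.5, c(2, 2, 5)), wl)
  expect_true(all(band_mean(const, band_range(500, 540)) == 2.5))
  expect_error(band_mean(cube, band_range(900, 950)), "no band centre")
  expect_error(band_range(700, 600), "lo_nm")
  expect_error(band_centred(520, 2), "odd")
})

test_that("band_mean is linear in the cube", {
  set.seed(4)
  a <- array(runif(24), c(2, 3, 4))
  b <- array(runif(24), c(2, 3, 4))
  wl <- c(400, 450, 500, 550)
  w <- band_centred(450, 3)
  lhs <- band_mean(hypercube(2 * a + 3 * b, wl), w)
  rhs <- 2 * band_mean(hypercube(a, wl), w) + 3 * band_mean(hypercube(b, wl), w)
  expect_equal(lhs, rhs)
})

test_that("normalised differences obey their closed form and bounds", {
  wl <- c(660, 720)
  red <- matrix(0.1, 3, 3); ir <- matrix(0.5, 3, 3)
  cube <- cube_from_bands(red, ir, wl = wl)
  expect_equal(ndvi(cube), matrix(0.4 / 0.6, 3, 3))

  eq <- cube_from_bands(matrix(2, 2, 2), matrix(2, 2, 2), wl = wl)
  expect_true(all(ndvi(eq) == 0))

  # 0/0 pixels carry no contrast and map to 0
  z <- cube_from_bands(matrix(0, 2, 2), matrix(0, 2, 2), wl = wl)
  expect_true(all(ndvi(z) == 0))

  ab <- cube_from_bands(matrix(3, 2, 2), matrix(1, 2, 2), wl = c(1000, 1100))
  expect_equal(normalized_difference(ab, band_centred(1000, 1), band_centred(1100, 1)),
               matrix(0.5, 2, 2))
  expect_true(all(normalized_difference(ab, band_centred(1000, 1),
                                        band_centred(1000, 1)) == 0))
})

test_that("normalised differences are antisymmetric and bounded on random cubes", {
  set.seed(5)
  for (i in 1:10) {
    arr <- array(runif(4 * 4 * 6, 0, 100), c(4, 4, 6))
    cube <- hypercube(arr, seq(1000, 1500, length.out = 6))
    wa <- band_centred(1100, 3); wb <- band_centred(1400, 3)
    nd <- normalized_difference(cube, wa, wb)
    expect_true(all(nd >= -1 & nd <= 1))
    expect_equal(normalized_difference(cube, wb, wa), -nd)
  }
})

test_that("default endmembers produce the index contrasts the pipeline relies on", {
  em <- default_endmembers()
  vnir_wl <- seq(400, 896, length.out = 178)
  swir_wl <- seq(895, 2506, length.out = 278)

  nd_of <- function(spec, wl, lo_a, hi_a, lo_b, hi_b) {
    a <- mean(spec[wl >= lo_a & wl <= hi_a]); b <- mean(spec[wl >= lo_b & wl <= hi_b])
    (a - b) / (a + b)
  }
  leaf_ndvi <- nd_of(em$vnir["leaf", ], vnir_wl, 710, 740, 650, 680)
  card_ndvi <- nd_of(em$vnir["cardboard", ], vnir_wl, 710, 740, 650, 680)
  expect_gte(leaf_ndvi, 0.6)
  expect_lte(card_ndvi, 0.1)

  nd3 <- function(spec, wl, c_a, c_b) {
    pick <- function(cn) sort(order(abs(wl - cn))[1:3])
    a <- mean(spec[pick(c_a)]); b <- mean(spec[pick(c_b)])
    (a - b) / (a + b)
  }
  expect_gt(nd3(em$swir["leaf", ], swir_wl, 1375, 1411),
            nd3(em$swir["cardboard", ], swir_wl, 1375, 1411))
  # tile is the low mode of the 1620/1537 white-reference index
  expect_lt(nd3(em$swir["tile", ], swir_wl, 1620, 1537),
            nd3(em$swir["cardboard", ], swir_wl, 1620, 1537))
  # tile reflectance dominates every other material on both grids
  for (g in c("vnir", "swir"))
    for (other in c("cardboard", "grass", "post", "leaf"))
      expect_true(all(em[[g]]["tile", ] >= em[[g]][other, ]))
})

test_that("simulator plant pixels score higher than background in both scanners", {
  sc <- generate_scene(tiny_cfg(seed = 21))
  nd <- ndvi(sc$vnir)
  expect_gt(mean(nd[sc$truth$vnir$plant_mask]),
            mean(nd[sc$truth$vnir$labels == 1]) + 0.5)
  pre <- index_preset("plant_swir")
  nds <- normalized_difference(sc$swir, pre$w_a, pre$w_b)
  expect_gt(mean(nds[sc$truth$swir$plant_mask]),
            mean(nds[sc$truth$swir$labels == 1]) + 0.05)
})
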