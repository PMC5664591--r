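# brute-force gradient: central differences, one-sided at the edges,
# rescaled by the global max |g|
brute_gradient <- function(img) {
  m <- nrow(img); n <- ncol(img)
  g <- img * 0
  for (x in 1:n) for (y in 1:m) {
    g[y, x] <- if (y == 1) img[2, x] - img[1, x]
    else if (y == m) img[m, x] - img[m - 1, x]
    else (img[y + 1, x] - img[y - 1, x]) / 2
  }
  if (max(abs(g)) > 0) g / max(abs(g)) else g
}

test_that("vertical gradient is normalised, signed and matches brute force", {
  expect_true(all(vertical_gradient(matrix(3, 4, 4)) == 0))
  ramp <- matrix(rep(1:6, 3), 6, 3)
  expect_true(all(vertical_gradient(ramp) == 1))

  set.seed(6)
  img <- matrix(runif(40), 8, 5)
  expect_equal(vertical_gradient(img), brute_gradient(img))

  # horizontal step edge: max |gradient| on the rows straddling the step
  step <- rbind(matrix(0, 3, 4), matrix(1, 3, 4))
  g <- vertical_gradient(step)
  expect_true(all(abs(g[c(3, 4), ]) == 1))
  expect_true(all(abs(g[c(1, 6), ]) == 0))
  expect_error(vertical_gradient(matrix(1, 1, 3)), "2 rows")
})

test_that("cost matrices follow their closed forms", {
  set.seed(7)
  img <- matrix(runif(48), 6, 8)
  g <- brute_gradient(img)
  ix <- colMeans(img)
  expect_equal(cost_grass_boundary(img),
               sweep(1 - g, 2, exp(-ix), `*`))
  expect_equal(cost_edge(img), 1 - g)
  expect_equal(cost_edge(img, "falling"), 1 + g)

  expect_true(all(cost_edge(matrix(5, 4, 4)) == 1))

  # zero column means collapse the grass cost onto the plain edge cost
  sym <- rbind(matrix(-1, 2, 5), matrix(1, 2, 5))
  expect_equal(cost_grass_boundary(sym), cost_edge(sym))

  d <- matrix(runif(48), 6, 8)
  expect_equal(cost_edge_with_shape(img, d, 0), cost_edge(img))
  expect_equal(cost_edge_with_shape(img, d, 0.7), cost_edge(img) + 0.7 * d)
  expect_error(cost_edge_with_shape(img, matrix(0, 2, 2), 0.1), "shapes")
})

test_that("an edge seam settles on the step for the matching polarity", {
  bright_above <- rbind(matrix(1, 3, 6), matrix(0, 3, 6))
  p <- min_cost_path(cost_edge(bright_above, "falling"), 0.05)
  expect_true(all(p$y %in% c(3, 4)))
  dark_above <- rbind(matrix(0, 3, 6), matrix(1, 3, 6))
  p2 <- min_cost_path(cost_edge(dark_above, "rising"), 0.05)
  expect_true(all(p2$y %in% c(3, 4)))
})

test_that("shape function is a per-column V anchored at the expected offset", {
  bottom <- min_cost_path(matrix(c(rep(1, 5), 0, rep(1, 2)), 8, 4), 0)
  expect_true(all(bottom$y == 6))
  d <- shape_function_from_edge(bottom, expected_width = 3, height = 8)
  expect_equal(dim(d), c(8L, 4L))
  expect_true(all(d[3, ] == 0))          # expected top edge: 6 - 3
  expect_true(all(d[2, ] == 1))
  expect_true(all(d[4, ] == 1))
  expect_true(all(d >= 0))
  expect_equal(d[, 1], abs(3 - (1:8)))
  expect_error(shape_function_from_edge(bottom, 10, 8), "above the image")
})

test_that("a flat image with a V-shaped distance penalty follows the V vertex", {
  img <- matrix(1, 10, 6)
  bottom <- structure(list(y = rep(8L, 6), total_cost = 0), class = "boundary_path")
  d <- shape_function_from_edge(bottom, expected_width = 4, height = 10)
  p <- min_cost_path(cost_edge_with_shape(img, d, lambda_dist = 0.5), 0.05)
  expect_true(all(p$y == 4))
})

test_that("zero cost yields a straight horizontal path", {
  p <- min_cost_path(matrix(0, 7, 9), 0.5)
  expect_equal(p$total_cost, 0)
  expect_true(all(p$y == p$y[1]))
})

test_that("single-column matrices return the per-column argmin", {
  C <- matrix(c(3, 1, 2), 3, 1)
  p <- min_cost_path(C, 0.1)
  expect_equal(p$y, 2L)
  expect_equal(p$total_cost, 1)
})

test_that("DP seam cost equals the exhaustive shortest-path oracle", {
  set.seed(8)
  for (i in 1:25) {
    m <- sample(2:12, 1); n <- sample(2:12, 1)
    C <- matrix(runif(m * n), m, n)
    for (lam in c(0, 0.1, 1, 10)) {
      p <- min_cost_path(C, lam)
      expect_true(all(abs(diff(p$y)) <= 1))
      expect_equal(p$total_cost, oracle_seam_cost(C, lam), tolerance = 1e-10)
    }
  }
})

test_that("larger vertical penalties never add diagonal moves", {
  set.seed(9)
  for (i in 1:10) {
    C <- matrix(runif(10 * 10), 10, 10)
    diags <- vapply(c(0, 0.1, 1, 10), function(lam) {
      sum(diff(min_cost_path(C, lam)$y) != 0)
    }, numeric(1))
    expect_true(all(diff(diags) <= 0))
  }
})
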