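#' Normalised vertical gradient of an image
#'
#' Central finite differences along y (one-sided at the top and bottom
#' rows), with y increasing downward, rescaled so the maximum absolute
#' gradient maps to 1. The rescaling makes every cost built on the
#' gradient scale-invariant to image brightness. A constant image returns
#' all zeros.
#'
#' @param img numeric matrix `[y, x]`, at least 2 rows.
#' @return Numeric matrix in `[-1, 1]`; positive where intensity increases
#'   downward.
#' @export
vertical_gradient <- function(img) {
  if (!is.matrix(img) || nrow(img) < 2L)
    stop("image must be a matrix with at least 2 rows", call. = FALSE)
  m <- nrow(img)
  g <- img
  g[1L, ] <- img[2L, ] - img[1L, ]
  g[m, ] <- img[m, ] - img[m - 1L, ]
  if (m > 2L) g[2:(m - 1L), ] <- (img[3:m, , drop = FALSE] - img[1:(m - 2L), , drop = FALSE]) / 2
  mx <- max(abs(g))
  if (mx > 0) g <- g / mx
  g
}

#' Cost matrices for boundary seams
#'
#' Per-pixel costs whose minimum-cost left-to-right seam marks a
#' horizontal boundary in the image. All costs are built from the
#' normalised vertical gradient `g_y` ([vertical_gradient()]); `polarity`
#' selects the edge direction the seam is attracted to: `"rising"` favours
#' edges that brighten downward (cost `1 - g_y`), `"falling"` edges that
#' darken downward (cost `1 + g_y`).
#'
#' * `cost_edge(img)`: `1 - s * g_y`, the plain edge cost.
#' * `cost_grass_boundary(ndvi_img)`: `exp(-I(x)) * (1 - g_y)` where
#'   `I(x)` is the column mean of the NDVI image. The brightness factor
#'   weakens the cost in columns where plants hide the cardboard/grass
#'   boundary, so the seam is not dragged away there. Equals `cost_edge`
#'   where the column means are zero.
#' * `cost_edge_with_shape(img, d, lambda_dist)`: `1 - s * g_y +
#'   lambda_dist * d`, the edge cost plus a distance penalty `d` that
#'   favours an edge at a known offset from an already-found seam.
#'
#' @param img,ndvi_img numeric matrix `[y, x]`.
#' @param polarity `"rising"` or `"falling"` edge direction.
#' @param d non-negative penalty matrix `[y, x]` from
#'   [shape_function_from_edge()].
#' @param lambda_dist non-negative weight of the distance penalty.
#' @return Numeric cost matrix `[y, x]`.
#' @export
cost_edge <- function(img, polarity = c("rising", "falling")) {
  polarity <- match.arg(polarity)
  s <- if (polarity == "rising") 1 else -1
  1 - s * vertical_gradient(img)
}

#' @rdname cost_edge
#' @export
cost_grass_boundary <- function(ndvi_img) {
  g <- vertical_gradient(ndvi_img)
  ix <- colMeans(ndvi_img)
  sweep(1 - g, 2L, exp(-ix), `*`)
}

#' @rdname cost_edge
#' @export
cost_edge_with_shape <- function(img, d, lambda_dist,
                                 polarity = c("rising", "falling")) {
  if (lambda_dist < 0) stop("`lambda_dist` must be >= 0", call. = FALSE)
  if (!identical(dim(img), dim(d)))
    stop("shape function and image have different shapes", call. = FALSE)
  cost_edge(img, polarity) + lambda_dist * d
}

#' Distance-penalty shape function from a detected edge
#'
#' Given the bottom edge of the white reference tile and its expected
#' width in pixels, builds the penalty `d(y, x) = |(bottom_y(x) -
#' expected_width) - y|`: a per-column V that is zero exactly where the
#' top edge is expected and grows linearly with vertical distance from it.
#'
#' @param bottom a [min_cost_path()] result (the bottom edge).
#' @param expected_width expected tile width in pixels, >= 1.
#' @param height image height in rows.
#' @return Numeric matrix `[y, x]` of non-negative penalties.
#' @export
shape_function_from_edge <- function(bottom, expected_width, height) {
  if (expected_width < 1) stop("`expected_width` must be >= 1", call. = FALSE)
  expected <- bottom$y - expected_width
  if (all(expected < 1))
    stop("expected top edge lies above the image in every column", call. = FALSE)
  outer(seq_len(height), expected, function(y, e) abs(e - y))
}

#' Minimum-cost continuous seam across an image
#'
#' Dynamic programming over the cost matrix: the cost `t(x, y)` of the
#' best path ending at `(x, y)` is `C(x, y)` in the first column and
#' otherwise `min(t(x-1, y-1) + C(x, y) + lambda_ver, t(x-1, y) + C(x, y),
#' t(x-1, y+1) + C(x, y) + lambda_ver)`, with off-image rows treated as
#' infinite cost. `lambda_ver` penalises each diagonal move, favouring
#' seams with limited vertical movement; with an all-zero cost matrix the
#' optimum is a straight horizontal line. The returned seam backtracks
#' from the minimum of the last column and always satisfies
#' `|y(x+1) - y(x)| <= 1`.
#'
#' Tie-breaking is deterministic: a horizontal move is preferred over an
#' upward move over a downward one, and the smallest row wins the final
#' argmin.
#'
#' @param C numeric cost matrix `[y, x]`, finite.
#' @param lambda_ver non-negative per-move vertical penalty.
#' @return A `boundary_path`: list with `y` (row index per column, 1-based)
#'   and `total_cost`.
#' @export
min_cost_path <- function(C, lambda_ver = 0.05) {
  if (!is.matrix(C) || !all(is.finite(C)))
    stop("cost matrix must be a finite numeric matrix", call. = FALSE)
  if (lambda_ver < 0) stop("`lambda_ver` must be >= 0", call. = FALSE)
  m <- nrow(C); n <- ncol(C)
  t_prev <- C[, 1L]
  off <- matrix(0L, m, n)  # predecessor row offset: pred_y = y + off[y, x]
  if (n > 1L) {
    for (x in 2:n) {
      from_above <- c(Inf, t_prev[-m]) + lambda_ver   # pred y-1, move down
      from_below <- c(t_prev[-1L], Inf) + lambda_ver  # pred y+1, move up
      best <- pmin(t_prev, from_below, from_above)
      o <- rep.int(-1L, m)
      o[from_below == best] <- 1L
      o[t_prev == best] <- 0L
      off[, x] <- o
      t_prev <- best + C[, x]
    }
  }
  y_end <- which.min(t_prev)
  path <- integer(n)
  path[n] <- y_end
  if (n > 1L) {
    for (x in n:2) path[x - 1L] <- path[x] + off[path[x], x]
  }
  structure(list(y = path, total_cost = t_prev[y_end]), class = "boundary_path")
}

#' @export
print.boundary_path <- function(x, ...) {
  cat(sprintf("<boundary_path> %d columns, rows %d-%d, total cost %.4g\n",
              length(x$y), min(x$y), max(x$y), x$total_cost))
  invisible(x)
}
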