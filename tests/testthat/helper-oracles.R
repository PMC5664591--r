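# Independent oracles used to cross-check the implementation.

# Shortest path over the explicit DAG of seam moves, via igraph's Dijkstra:
# nodes (x, y); edges (x, y) -> (x+1, y + {-1,0,1}) weighted
# C(x+1, y') plus lambda for diagonal moves; a virtual source feeds column 1
# at weight C(1, y) and a virtual sink drains the last column at weight 0.
oracle_seam_cost <- function(C, lambda_ver) {
  m <- nrow(C); n <- ncol(C)
  id <- function(x, y) (x - 1L) * m + y
  src <- n * m + 1L; snk <- n * m + 2L
  from <- c(); to <- c(); w <- c()
  for (y in 1:m) {
    from <- c(from, src); to <- c(to, id(1L, y)); w <- c(w, C[y, 1L])
  }
  if (n > 1L) {
    for (x in 1:(n - 1L)) for (y in 1:m) for (dy in -1:1) {
      y2 <- y + dy
      if (y2 >= 1L && y2 <= m) {
        from <- c(from, id(x, y)); to <- c(to, id(x + 1L, y2))
        w <- c(w, C[y2, x + 1L] + if (dy != 0L) lambda_ver else 0)
      }
    }
  }
  for (y in 1:m) {
    from <- c(from, id(n, y)); to <- c(to, snk); w <- c(w, 0)
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  as.numeric(igraph::distances(g, v = src, to = snk, mode = "out", weights = w))
}

# Brute-force 3x3 cross erosion: per-pixel neighbourhood check with
# out-of-image neighbours counted as false.
oracle_erode_cross <- function(mask) {
  m <- nrow(mask); n <- ncol(mask)
  out <- mask
  at <- function(y, x) y >= 1 && y <= m && x >= 1 && x <= n && mask[y, x]
  for (y in 1:m) for (x in 1:n) {
    out[y, x] <- mask[y, x] && at(y - 1, x) && at(y + 1, x) &&
      at(y, x - 1) && at(y, x + 1)
  }
  out
}

# Brute-force Otsu: for every histogram bin boundary compute the two-class
# between-class variance directly from the pixel values and return the
# boundary maximising it.
oracle_otsu <- function(img, n_bins = 256L) {
  v <- as.vector(img)
  edges <- seq(min(v), max(v), length.out = n_bins + 1L)
  best <- -Inf; best_thr <- NA_real_
  for (k in 1:(n_bins - 1L)) {
    thr <- edges[k + 1L]
    bin <- findInterval(v, edges, rightmost.closed = TRUE)
    lo <- v[bin <= k]; hi <- v[bin > k]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    # means of the binned representatives, matching the histogram formulation
    mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
    mu0 <- mean(mids[pmin(bin[bin <= k], n_bins)])
    mu1 <- mean(mids[pmin(bin[bin > k], n_bins)])
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best + 1e-12) { best <- sb; best_thr <- thr }
  }
  best_thr
}
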