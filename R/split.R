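#' Column-wise plant-pixel profile
#'
#' Number of pixels classified as plant in each image column. Peaks of the
#' profile correspond to plants, minima to the gaps between them.
#'
#' @param mask logical plant mask.
#' @return Integer vector of length `ncol(mask)`.
#' @export
column_profile <- function(mask) {
  validate_mask(mask)
  as.integer(colSums(mask))
}

smooth_profile <- function(profile, expected_spacing_px) {
  w <- max(1L, round(0.1 * expected_spacing_px))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) return(as.numeric(profile))
  s <- as.numeric(stats::filter(profile, rep(1 / w, w), sides = 2L))
  s[is.na(s)] <- profile[is.na(s)]
  s
}

#' Find plant peaks in a column profile
#'
#' Local maxima of the smoothed profile (moving average of width 10% of
#' the expected spacing), kept greedily in decreasing height order subject
#' to a pairwise minimum distance of 80% of the expected plant separation.
#' Height ties go to the leftmost peak. Positions are 0-based columns,
#' sorted ascending.
#'
#' @param profile integer vector from [column_profile()].
#' @param expected_spacing_px expected plant separation in pixels, >= 2.
#' @return Integer vector of 0-based peak columns (possibly empty).
#' @export
find_plant_peaks <- function(profile, expected_spacing_px) {
  if (length(profile) == 0L) stop("empty profile", call. = FALSE)
  if (expected_spacing_px < 2) stop("`expected_spacing_px` must be >= 2", call. = FALSE)
  s <- smooth_profile(profile, expected_spacing_px)
  n <- length(s)
  if (all(s == 0)) return(integer(0))
  ## local maxima; plateaus contribute their centre column
  cand <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1L] == s[i]) j <- j + 1L
    left_ok <- i == 1L || s[i - 1L] < s[i]
    right_ok <- j == n || s[j + 1L] < s[i]
    if (left_ok && right_ok && s[i] > 0) cand <- c(cand, (i + j) %/% 2L)
    i <- j + 1L
  }
  if (length(cand) == 0L) return(integer(0))
  ord <- cand[order(-s[cand], cand)]
  min_d <- 0.8 * expected_spacing_px
  kept <- integer(0)
  for (p in ord) {
    if (all(abs(kept - p) >= min_d)) kept <- c(kept, p)
  }
  sort(kept) - 1L
}

#' Split a row image into individual plant regions
#'
#' From the plant-pixel profile of the full row:
#' 1. peaks are located with [find_plant_peaks()];
#' 2. provisional boundaries are placed midway between consecutive peaks,
#'    plus the two image ends;
#' 3. any inter-peak gap wider than 1.5x the expected spacing is
#'    subdivided into `round(gap / spacing)` equal regions, catching
#'    plants the peak finder missed;
#' 4. the region count is matched to the known plant count by merging the
#'    region with the fewest plant pixels into its lower-profile
#'    neighbour, or splitting the widest region at its internal profile
#'    minimum;
#' 5. every internal boundary is moved to the profile's local minimum
#'    within +/- 0.25x the spacing (ties resolved toward the provisional
#'    boundary), the optimum place to cut;
#' 6. the analysis span shaves 10% of each region's width from both sides
#'    to exclude areas where neighbouring bushes intermingle.
#'
#' The returned regions tile `[0, width)` exactly and are numbered by
#' position.
#'
#' @param profile integer vector from [column_profile()].
#' @param n_expected known number of plants in the image, >= 1.
#' @param expected_spacing_px expected plant separation in pixels;
#'   defaults to `width / n_expected`.
#' @return Data frame with columns `plant_id`, `full_start`, `full_end`,
#'   `analysis_start`, `analysis_end` (0-based, half-open).
#' @export
split_row <- function(profile, n_expected, expected_spacing_px = NULL) {
  width <- length(profile)
  if (n_expected < 1L) stop("`n_expected` must be >= 1", call. = FALSE)
  if (width < n_expected)
    stop(sprintf("image width (%d) is narrower than n_expected (%d)", width, n_expected),
         call. = FALSE)
  if (is.null(expected_spacing_px)) expected_spacing_px <- width / n_expected
  spacing <- expected_spacing_px
  profile <- as.numeric(profile)

  peaks <- if (spacing >= 2) find_plant_peaks(profile, spacing) else integer(0)

  ## (2) + (3): boundaries between peaks, subdividing oversized gaps
  bounds <- c(0)
  if (length(peaks) >= 2L) {
    for (i in seq_len(length(peaks) - 1L)) {
      gap <- peaks[i + 1L] - peaks[i]
      if (gap > 1.5 * spacing) {
        k <- max(2L, round(gap / spacing))
        cuts <- peaks[i] + gap * seq_len(k - 1L) / k
      } else {
        cuts <- (peaks[i] + peaks[i + 1L]) / 2
      }
      bounds <- c(bounds, floor(cuts))
    }
  }
  bounds <- sort(unique(c(bounds, width)))
  bounds <- bounds[bounds >= 0 & bounds <= width]
  ## drop degenerate zero-width regions
  bounds <- unique(bounds)

  region_sum <- function(b) {
    vapply(seq_len(length(b) - 1L), function(i) {
      sum(profile[(b[i] + 1L):b[i + 1L]])
    }, numeric(1))
  }

  ## (4) match the region count to the known plant count
  repeat {
    n_reg <- length(bounds) - 1L
    if (n_reg == n_expected) break
    if (n_reg > n_expected) {
      sums <- region_sum(bounds)
      i <- which.min(sums)                      # fewest plant pixels
      left_s <- if (i > 1L) sums[i - 1L] else Inf
      right_s <- if (i < n_reg) sums[i + 1L] else Inf
      drop_bound <- if (left_s <= right_s) i else i + 1L
      bounds <- bounds[-drop_bound]
    } else {
      widths <- diff(bounds)
      i <- which.max(widths)                    # widest region
      lo <- bounds[i]; hi <- bounds[i + 1L]
      if (hi - lo < 2L)
        stop("cannot split further: regions are single columns", call. = FALSE)
      interior <- (lo + 1L):(hi - 1L)           # internal cut candidates
      centre <- (lo + hi) / 2                   # ties -> nearest region centre
      cut <- interior[order(profile[interior + 1L],
                            abs(interior - centre), interior)][1L]
      bounds <- sort(c(bounds, cut))
    }
  }

  ## (5) refine internal boundaries to local minima of the profile
  if (n_expected > 1L) {
    halfwin <- 0.25 * spacing
    for (i in 2:(length(bounds) - 1L)) {
      b <- bounds[i]
      lo <- max(bounds[i - 1L] + 1L, ceiling(b - halfwin))
      hi <- min(bounds[i + 1L] - 1L, floor(b + halfwin))
      if (lo > hi) next
      cand <- lo:hi
      vals <- profile[cand + 1L]
      best <- cand[order(vals, abs(cand - b), cand)][1L]
      bounds[i] <- best
    }
  }

  full_start <- bounds[-length(bounds)]
  full_end <- bounds[-1L]
  w <- full_end - full_start
  shave <- round(0.1 * w)
  analysis_start <- pmin(full_start + shave, full_end - 1L)
  analysis_end <- pmax(full_end - shave, analysis_start + 1L)
  data.frame(plant_id = seq_len(n_expected),
             full_start = as.integer(full_start),
             full_end = as.integer(full_end),
             analysis_start = as.integer(analysis_start),
             analysis_end = as.integer(analysis_end))
}
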