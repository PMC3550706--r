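#' Wrap-aware angular row distance
#'
#' The A-line (row) axis of a polar frame is circular: row 1 and row
#' `n_alines` are neighbours. The angular distance between two rows is the
#' shorter way around.
#'
#' @param r1,r2 Row indices (1-based); vectors are recycled.
#' @param n_alines Number of A-lines per frame.
#' @return Non-negative numeric vector of wrap-aware row differences.
#' @export
wrap_row_dist <- function(r1, r2, n_alines) {
  d <- abs(r1 - r2)
  pmin(d, n_alines - d)
}

#' Wrap-aware Euclidean pixel distance
#'
#' Euclidean distance on (row, depth) pixel coordinates with the row
#' difference taken modulo the angular wrap. This is the metric used for
#' clustering, guide-wire continuity and detection/ground-truth matching.
#'
#' @param a1,d1 Row and depth of the first point(s).
#' @param a2,d2 Row and depth of the second point(s).
#' @param n_alines Number of A-lines per frame.
#' @return Numeric vector of distances in pixels.
#' @export
pixel_dist <- function(a1, d1, a2, d2, n_alines) {
  dr <- wrap_row_dist(a1, a2, n_alines)
  sqrt(dr^2 + (d1 - d2)^2)
}

#' Circular mean of row coordinates
#'
#' Rows are mapped to angles on the unit circle, averaged as vectors, and
#' mapped back, so that e.g. rows just above 1 and just below `n_alines`
#' average near the seam rather than in the middle of the frame.
#'
#' @param rows Row indices (1-based).
#' @param n_alines Number of A-lines per frame.
#' @return The circular mean row as a real number in `[0.5, n_alines + 0.5)`
#'   scale; use [round()] for a pixel row.
#' @export
circular_mean_row <- function(rows, n_alines) {
  theta <- (rows - 1) / n_alines * 2 * pi
  m <- atan2(mean(sin(theta)), mean(cos(theta)))
  r <- ((m / (2 * pi)) * n_alines) %% n_alines
  if (n_alines - r < 1e-9) r <- 0  # guard the seam against fp drift
  r + 1
}

#' Forward (clockwise) angular distance from one row to another
#'
#' Distance walked from `from` towards increasing row index, wrapping at
#' `n_alines`, until `to` is reached. Used for the "first cluster below a
#' top edge / above a bottom edge" selection rule.
#'
#' @param from,to Row indices.
#' @param n_alines Number of A-lines per frame.
#' @return Value in `[0, n_alines)`.
#' @keywords internal
forward_row_dist <- function(from, to, n_alines) {
  (to - from) %% n_alines
}

#' Rank-based percentile of an intensity sample
#'
#' Order statistic at rank `ceiling(p * N)` of the sorted sample (no
#' interpolation), the convention used for both the noise floor and the
#' maximum shadow intensity threshold on integer 16-bit data.
#'
#' @param x Numeric/integer vector of intensities.
#' @param p Fraction in (0, 1).
#' @return A single intensity value present in `x`.
#' @export
intensity_percentile <- function(x, p) {
  stopifnot(length(x) > 0, p > 0, p < 1)
  stats::quantile(x, probs = p, type = 1, names = FALSE)
}

# Union-find with path compression; used by clustering and edge merging.
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

uf_labels <- function(parent) {
  roots <- vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
  match(roots, unique(roots))
}

# Automatic edge-strength threshold: a multiple of the robust noise scale
# (MAD-based sigma) of the non-zero responses. The response histogram is
# unimodal speckle noise around zero with a long tail of true edge
# responses, whose strength spans orders of magnitude (it scales with the
# local tissue brightness, which attenuates with depth); a noise-scale
# threshold keeps even deep, dim shadow edges continuous while isolated
# noise exceedances remain short and fall to the edge length filter. A
# floor of 5% of the peak response guards near-noiseless frames, where
# the MAD estimate degenerates towards zero and the faint smoothing tails
# of an edge would otherwise count as edges themselves.
# Returns NA when the frame has no usable response.
auto_response_threshold <- function(x, k = 3) {
  nz <- x[x != 0]
  if (length(nz) < 2L) return(NA_real_)
  mx <- max(nz)
  if (mx <= 0) return(NA_real_)
  sigma <- 1.4826 * stats::median(abs(nz))
  max(k * sigma, 0.05 * mx)
}

empty_strut_df <- function() {
  data.frame(
    frame = integer(0), aline = integer(0), depth = integer(0),
    kind = character(0), stringsAsFactors = FALSE
  )
}
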