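#' Gaussian smoothing of a polar frame
#'
#' 2D Gaussian convolution with a normalized separable kernel. The angular
#' (row) axis is periodic, so it uses wrap boundary conditions; the depth
#' axis is reflected at its borders.
#'
#' @param frame Numeric matrix `[aline, depth]`.
#' @param sigma Kernel standard deviation in pixels.
#' @return A real-valued matrix of the same shape.
#' @export
smooth_frame <- function(frame, sigma) {
  stopifnot(sigma > 0)
  r <- ceiling(3 * sigma)
  g <- stats::dnorm(-r:r, sd = sigma)
  g <- g / sum(g)
  K <- outer(g, g)
  conv2_wrap_reflect(frame, K)
}

# FFT convolution with circular boundary on rows (angular wrap) and
# reflected padding on columns (depth).
conv2_wrap_reflect <- function(frame, K) {
  n <- ncol(frame)
  r <- (ncol(K) - 1L) / 2L
  r <- min(r, n - 1L)
  pad_left <- frame[, seq(r, 1L), drop = FALSE]
  pad_right <- frame[, seq(n, n - r + 1L), drop = FALSE]
  padded <- cbind(pad_left, frame, pad_right)
  res <- EBImage::filter2(padded, K, boundary = "circular")
  out <- res[, (r + 1L):(r + n), drop = FALSE]
  as.matrix(out)
}

# 3x3 horizontal Prewitt compass kernels. EBImage::filter2 performs true
# convolution (flips the kernel), so the row of +1 weights multiplies the
# row ABOVE the output pixel: the "top" kernel responds positively where
# the row above is brighter than the row below (bright-to-dark downward).
prewitt_kernel <- function(kind = c("top", "bottom")) {
  kind <- match.arg(kind)
  K <- rbind(c(-1, -1, -1), c(0, 0, 0), c(1, 1, 1))
  if (kind == "bottom") K <- -K
  K
}

#' Directional compass edge response
#'
#' Convolves a (smoothed) frame with one of two horizontal Prewitt compass
#' kernels. The `"top"` kernel is sensitive only to horizontal bright-to-
#' dark transitions going downward in row order (the top edge of a trailing
#' shadow); the `"bottom"` kernel is its negation and responds to
#' dark-to-bright transitions (the bottom edge). Rows wrap, depth reflects.
#'
#' @param frame Numeric matrix `[aline, depth]`, typically smoothed.
#' @param kind `"top"` or `"bottom"`.
#' @return A signed response matrix of the same shape.
#' @export
compass_response <- function(frame, kind = c("top", "bottom")) {
  kind <- match.arg(kind)
  conv2_wrap_reflect(frame, prewitt_kernel(kind))
}

#' Extract long shadow edges from a compass response
#'
#' Supra-threshold response pixels are grouped into per-row runs along the
#' depth axis; runs on rows at most one apart (wrap-aware) with overlapping
#' depth spans merge into one edge, tolerating slightly tilted shadows.
#' Each merged edge is positioned on its strongest-response run (the
#' physical transition row) and its length is the longest run's extent. Only edges at least
#' `length_threshold` pixels long survive, which suppresses the short false
#' edges produced by e.g. an eccentric lumen boundary.
#'
#' @param response Signed response matrix from [compass_response()].
#' @param response_threshold Absolute threshold; `NULL` picks three times
#'   the robust (MAD-based) noise scale of the response automatically.
#' @param length_threshold Minimum edge length in pixels.
#' @param kind Edge kind label stored on the result.
#' @return A `data.frame` with columns `kind`, `aline`, `depth_start`,
#'   `depth_end`, `length`.
#' @export
extract_edges <- function(response, response_threshold = NULL,
                          length_threshold, kind = "top") {
  n_alines <- nrow(response)
  thr <- response_threshold
  if (is.null(thr)) thr <- auto_response_threshold(response)
  empty <- data.frame(kind = character(0), aline = integer(0),
                      depth_start = integer(0), depth_end = integer(0),
                      length = integer(0), stringsAsFactors = FALSE)
  if (is.na(thr)) return(empty)
  runs <- list()
  for (a in seq_len(n_alines)) {
    above <- response[a, ] > thr
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    for (k in keep)
      runs[[length(runs) + 1L]] <- c(a, starts[k], ends[k])
  }
  if (!length(runs)) return(empty)
  runs <- do.call(rbind, runs)
  colnames(runs) <- c("row", "d1", "d2")
  nr <- nrow(runs)
  parent <- uf_new(nr)
  # group run indices by row for adjacency lookups (rows wrap)
  by_row <- split(seq_len(nr), runs[, "row"])
  for (i in seq_len(nr)) {
    rows_near <- ((runs[i, "row"] - 1L + c(0L, 1L)) %% n_alines) + 1L
    for (rn in rows_near) {
      js <- by_row[[as.character(rn)]]
      if (is.null(js)) next
      for (j in js) {
        if (j == i) next
        if (runs[i, "d1"] <= runs[j, "d2"] && runs[j, "d1"] <= runs[i, "d2"])
          parent <- uf_union(parent, i, j)
      }
    }
  }
  labels <- uf_labels(parent)
  edges <- lapply(split(seq_len(nr), labels), function(idx) {
    lens <- runs[idx, "d2"] - runs[idx, "d1"] + 1L
    strength <- vapply(idx, function(i)
      max(response[runs[i, "row"], runs[i, "d1"]:runs[i, "d2"]]), numeric(1))
    best <- idx[which.max(strength)]
    data.frame(kind = kind, aline = as.integer(runs[best, "row"]),
               depth_start = as.integer(runs[best, "d1"]),
               depth_end = as.integer(runs[best, "d2"]),
               length = as.integer(max(lens)), stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, edges)
  rownames(edges) <- NULL
  edges[edges$length >= length_threshold, , drop = FALSE]
}

#' Pair top and bottom shadow edges into intervals
#'
#' A trailing shadow is bounded by a top edge and, further along the
#' angular axis (wrapping at the frame seam), a bottom edge. Tops are
#' processed in row order and each claims the nearest unclaimed bottom at a
#' greater angular position modulo `n_alines`. Unpaired edges yield
#' one-sided intervals, since sometimes only one edge of a shadow is
#' detectable.
#'
#' @param tops,bottoms Edge `data.frame`s from [extract_edges()].
#' @param n_alines Number of A-lines per frame.
#' @return A `data.frame` with one interval per row: `top_aline`,
#'   `bottom_aline` (either may be `NA`), `top_start`, `bottom_start`
#'   (depth start columns of the edges), `span` (wrap-aware row span,
#'   `NA` for one-sided intervals).
#' @export
pair_edges <- function(tops, bottoms, n_alines) {
  nt <- if (is.null(tops)) 0L else nrow(tops)
  nb <- if (is.null(bottoms)) 0L else nrow(bottoms)
  out <- list()
  claimed <- rep(FALSE, nb)
  if (nt) {
    for (i in order(tops$aline)) {
      t_row <- tops$aline[i]
      pick <- NA_integer_
      if (nb && any(!claimed)) {
        open <- which(!claimed)
        fd <- forward_row_dist(t_row, bottoms$aline[open], n_alines)
        pick <- open[which.min(fd)]
        claimed[pick] <- TRUE
      }
      out[[length(out) + 1L]] <- data.frame(
        top_aline = t_row,
        bottom_aline = if (is.na(pick)) NA_integer_ else bottoms$aline[pick],
        top_start = tops$depth_start[i],
        bottom_start = if (is.na(pick)) NA_integer_ else bottoms$depth_start[pick],
        span = if (is.na(pick)) NA_real_
               else forward_row_dist(t_row, bottoms$aline[pick], n_alines))
    }
  }
  if (nb && any(!claimed)) {
    for (j in which(!claimed)) {
      out[[length(out) + 1L]] <- data.frame(
        top_aline = NA_integer_, bottom_aline = bottoms$aline[j],
        top_start = NA_integer_, bottom_start = bottoms$depth_start[j],
        span = NA_real_)
    }
  }
  if (!length(out)) {
    return(data.frame(top_aline = integer(0), bottom_aline = integer(0),
                      top_start = integer(0), bottom_start = integer(0),
                      span = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Is angular row `row` inside the wrap-aware span of a two-sided interval?
interval_contains <- function(top_aline, bottom_aline, row, n_alines) {
  span <- forward_row_dist(top_aline, bottom_aline, n_alines)
  forward_row_dist(top_aline, row, n_alines) <= span
}
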