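#' Maximum shadow intensity threshold
#'
#' Trailing shadows are the darkest structures of the ROI; the maximum
#' intensity a shadow pixel may take is defined as a percentile (by default
#' the 89th) of the intensity histogram of the ROI over the entire
#' pullback, using the same rank convention as the noise floor.
#'
#' @param pullback An `"oct_pullback"` (after noise flooring).
#' @param roi A `"roi_boundary"`.
#' @param percentile Fraction in (0, 1); default 0.89.
#' @return A single intensity threshold.
#' @export
compute_shadow_intensity_threshold <- function(pullback, roi,
                                               percentile = 0.89) {
  stopifnot(inherits(pullback, "oct_pullback"), inherits(roi, "roi_boundary"))
  if (roi$first_column > pullback$n_depth) stop("empty ROI")
  vals <- pullback$data[, roi$first_column:pullback$n_depth, , drop = FALSE]
  intensity_percentile(vals, percentile)
}

#' Peak of one A-line inside the ROI
#'
#' @param frame Integer matrix `[aline, depth]`.
#' @param aline Row index.
#' @param roi A `"roi_boundary"`.
#' @return `list(peak_depth, peak_intensity)` or `NULL` when the whole
#'   row is zero. Ties are broken towards the smallest depth (the strut
#'   front edge is the quantity of interest).
#' @export
find_aline_peak <- function(frame, aline, roi) {
  b <- roi$first_column
  v <- frame[aline, ]
  if (b > 1) v[seq_len(b - 1L)] <- 0L
  if (all(v == 0)) return(NULL)
  d <- which.max(v)  # first maximum = smallest depth
  list(peak_depth = as.integer(d), peak_intensity = as.numeric(v[d]))
}

#' Start of the trailing shadow behind a depth position
#'
#' The potential shadow is a window of `window` continuous pixels at or
#' below `shadow_threshold`. The search starts just behind `from_depth`
#' and returns the first depth at which such a window begins. At the far
#' image edge a truncated window is accepted when at least half the window
#' remains, so deep struts near the border still cast a usable shadow.
#'
#' @param frame Integer matrix `[aline, depth]`.
#' @param aline Row index.
#' @param from_depth Column behind which to search (exclusive).
#' @param shadow_threshold Maximum shadow intensity.
#' @param window Window length in pixels.
#' @return The shadow start column, or `NULL` when no window qualifies.
#' @export
find_shadow_start <- function(frame, aline, from_depth, shadow_threshold,
                              window) {
  stopifnot(window >= 1)
  v <- frame[aline, ]
  n <- length(v)
  if (from_depth >= n) return(NULL)
  low <- v <= shadow_threshold
  # run[d] = length of the low run starting at d
  run <- integer(n)
  if (low[n]) run[n] <- 1L
  if (n > 1) for (d in (n - 1):1) if (low[d]) run[d] <- run[d + 1L] + 1L
  half <- ceiling(window / 2)
  for (d in (from_depth + 1L):n) {
    if (run[d] >= window) return(as.integer(d))
    if (run[d] >= half && d + run[d] - 1L == n) return(as.integer(d))
  }
  NULL
}

#' Candidate strut pixels of one frame
#'
#' Each A-line contributes at most one candidate: its intensity peak,
#' provided a trailing shadow window is found behind it and the two-point
#' slope from the peak down to the shadow start,
#' `(I(shadow_start) - peak) / dist`, is at or below (steeper than) the
#' slope threshold. Strut pixels fall off to their shadow much faster than
#' tissue attenuates, which is what the slope criterion captures.
#'
#' @param frame Integer matrix `[aline, depth]` (noise-floored; masked to
#'   the ROI internally).
#' @param roi A `"roi_boundary"`.
#' @param shadow_threshold Maximum shadow intensity.
#' @param slope_threshold Negative slope cut-off (intensity units/pixel).
#' @param window Sliding shadow window length in pixels.
#' @return A `data.frame` with one row per candidate: `aline`,
#'   `peak_depth`, `peak_intensity`, `shadow_start`, `dist`, `slope`.
#' @export
detect_candidates <- function(frame, roi, shadow_threshold, slope_threshold,
                              window) {
  frame <- apply_roi(frame, roi)
  out <- vector("list", nrow(frame))
  for (a in seq_len(nrow(frame))) {
    pk <- find_aline_peak(frame, a, roi)
    if (is.null(pk)) next
    ss <- find_shadow_start(frame, a, pk$peak_depth, shadow_threshold, window)
    if (is.null(ss)) next
    dist <- ss - pk$peak_depth
    slope <- (frame[a, ss] - pk$peak_intensity) / dist
    if (slope <= slope_threshold) {
      out[[a]] <- data.frame(aline = a, peak_depth = pk$peak_depth,
                             peak_intensity = pk$peak_intensity,
                             shadow_start = ss, dist = dist, slope = slope)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(aline = integer(0), peak_depth = integer(0),
                      peak_intensity = numeric(0), shadow_start = integer(0),
                      dist = integer(0), slope = numeric(0)))
  }
  do.call(rbind, out)
}
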