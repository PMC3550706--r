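#' Global noise floor of a pullback
#'
#' The low-intensity tail of the pullback histogram is dominated by noise;
#' the floor is the order statistic at rank `ceiling(p * N)` over every
#' pixel of every frame. Pixels strictly below the returned value are
#' treated as noise.
#'
#' @param pullback An `"oct_pullback"`.
#' @param noise_percentile Fraction of pixels regarded as noise (default
#'   0.05, i.e. the lowest 5 percent of the histogram).
#' @return A single intensity threshold.
#' @export
compute_noise_floor <- function(pullback, noise_percentile = 0.05) {
  stopifnot(inherits(pullback, "oct_pullback"))
  if (length(pullback$data) == 0L) stop("empty pullback")
  intensity_percentile(pullback$data, noise_percentile)
}

#' Zero all pixels below the noise floor
#'
#' @param pullback An `"oct_pullback"`.
#' @param t Intensity threshold; pixels with intensity `< t` become 0,
#'   others are unchanged.
#' @return A noise-floored `"oct_pullback"` of identical shape.
#' @export
apply_noise_floor <- function(pullback, t) {
  stopifnot(inherits(pullback, "oct_pullback"), t >= 0)
  d <- pullback$data
  d[d < t] <- 0L
  oct_pullback(d, pixel_size_mm = pullback$pixel_size_mm)
}

#' Region-of-interest boundary excluding catheter ring artifacts
#'
#' Catheter ring artifacts appear in polar frames as bright vertical lines
#' near the left (catheter-side) edge, constant across all frames of a
#' pullback. A minimum projection along the pullback (z) axis suppresses
#' moving tissue while constant artifacts survive; depth columns of the
#' z-minimum image whose rows are almost all above the noise floor are
#' flagged as artifact lines within the leftmost search window. The ROI
#' starts one column right of the rightmost flagged line.
#'
#' @param pullback An `"oct_pullback"` (noise-floored or raw).
#' @param noise_floor Intensity threshold from [compute_noise_floor()].
#' @param line_row_fraction Fraction of rows that must exceed the noise
#'   floor for a column to count as an artifact line.
#' @param search_fraction Leftmost fraction of depth columns searched.
#' @return A list of class `"roi_boundary"` with `first_column` (the first
#'   depth column inside the ROI; 1 when no artifact is found) and the
#'   flagged `line_columns`.
#' @export
compute_catheter_boundary <- function(pullback, noise_floor,
                                      line_row_fraction = 0.95,
                                      search_fraction = 0.25) {
  stopifnot(inherits(pullback, "oct_pullback"))
  zmin <- pullback$data[, , 1, drop = TRUE]
  if (pullback$n_frames > 1) {
    for (f in 2:pullback$n_frames)
      zmin <- pmin(zmin, pullback$data[, , f, drop = TRUE])
  }
  frac_above <- colMeans(zmin > noise_floor)
  window_end <- max(1L, ceiling(search_fraction * pullback$n_depth))
  line_cols <- which(frac_above > line_row_fraction)
  line_cols <- line_cols[line_cols <= window_end]
  first_column <- if (length(line_cols)) max(line_cols) + 1L else 1L
  structure(list(first_column = as.integer(first_column),
                 line_columns = as.integer(line_cols)),
            class = "roi_boundary")
}

#' @export
print.roi_boundary <- function(x, ...) {
  cat(sprintf("ROI boundary: depth columns >= %d (%d artifact line column(s))\n",
              x$first_column, length(x$line_columns)))
  invisible(x)
}

#' Mask a frame to the region of interest
#'
#' @param frame Integer matrix `[aline, depth]`.
#' @param roi A `"roi_boundary"` from [compute_catheter_boundary()].
#' @return The frame with columns left of `roi$first_column` zeroed.
#' @export
apply_roi <- function(frame, roi) {
  stopifnot(inherits(roi, "roi_boundary"))
  b <- roi$first_column
  if (b > 1) frame[, seq_len(min(b - 1L, ncol(frame)))] <- 0L
  frame
}
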