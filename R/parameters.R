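#' Detection parameters
#'
#' Bundles every tunable of the strut detection pipeline. Defaults are the
#' published operating point for full-size polar frames (504 A-lines x 960
#' depth samples); use [scale_parameters()] to adapt the pixel-valued
#' thresholds to other frame geometries.
#'
#' @param noise_percentile Fraction of the global pullback histogram treated
#'   as noise; pixels below the corresponding order statistic are zeroed.
#' @param shadow_intensity_percentile Percentile (of the ROI histogram over
#'   the whole pullback) defining the maximum intensity of a trailing
#'   shadow.
#' @param shadow_threshold_scale Multiplier applied to the computed shadow
#'   intensity threshold (1 leaves it unchanged; used by sensitivity
#'   sweeps).
#' @param sliding_shadow_size Length in pixels of the window of continuous
#'   low-intensity pixels that defines a potential shadow along an A-line.
#' @param slope_threshold Maximum (most shallow) accepted slope, in raw
#'   intensity units per pixel, between an A-line peak and the start of its
#'   trailing shadow. Must be negative; candidates need a slope at or below
#'   (steeper than) this value.
#' @param gaussian_sigma Standard deviation in pixels of the Gaussian
#'   smoothing applied before shadow edge detection.
#' @param edge_response_threshold Absolute threshold on the compass edge
#'   response. `NULL` (default) selects, per frame and response image,
#'   three times the robust (MAD) noise scale of the response.
#' @param edge_length_threshold Minimum depth extent in pixels of an
#'   accepted shadow edge.
#' @param clustering_distance_threshold Candidate pixels closer than this
#'   (wrap-aware Euclidean, pixels) merge into one cluster.
#' @param guide_wire_distance_threshold Maximum frame-to-frame displacement
#'   in pixels for the guide-wire continuity chain.
#' @param acceptance_distance Matching tolerance in pixels between a
#'   detection and a reference strut (also used to associate detections with
#'   the guide-wire track).
#' @param line_row_fraction Fraction of rows of the z-minimum image that
#'   must exceed the noise floor for a depth column to count as a catheter
#'   artifact line.
#' @param catheter_search_fraction Leftmost fraction of depth columns
#'   searched for catheter artifact lines.
#' @param non_bright_depth_back,non_bright_depth_fwd Depth window (pixels
#'   before/after the shadow edge start column) searched when recovering a
#'   non-bright strut.
#' @param min_non_bright_pixels Minimum number of supra-threshold pixels for
#'   a recovered non-bright strut.
#' @param min_track_fraction Minimum fraction of frames a continuous chain
#'   must cover to be accepted as the guide wire.
#' @param guide_wire_max_gap Maximum number of frames a guide-wire chain
#'   link may bridge (a missed frame does not sever the track).
#' @param segment_min_count Minimum smoothed per-frame strut count inside
#'   the stented segment.
#' @param segment_smooth_window Moving-average window (frames) for the
#'   per-frame strut counts.
#' @param pixel_size_mm Physical depth-pixel size; 10 pixels correspond to
#'   about 0.05 mm.
#'
#' @return A list of class `"detection_parameters"`.
#' @seealso [scale_parameters()], [read_config()]
#' @export
detection_parameters <- function(noise_percentile = 0.05,
                                 shadow_intensity_percentile = 0.89,
                                 shadow_threshold_scale = 1,
                                 sliding_shadow_size = 30,
                                 slope_threshold = -48,
                                 gaussian_sigma = 1.5,
                                 edge_response_threshold = NULL,
                                 edge_length_threshold = 100,
                                 clustering_distance_threshold = 4,
                                 guide_wire_distance_threshold = 40,
                                 acceptance_distance = 10,
                                 line_row_fraction = 0.95,
                                 catheter_search_fraction = 0.25,
                                 non_bright_depth_back = 10,
                                 non_bright_depth_fwd = 30,
                                 min_non_bright_pixels = 2,
                                 min_track_fraction = 0.8,
                                 guide_wire_max_gap = 2,
                                 segment_min_count = 3,
                                 segment_smooth_window = 5,
                                 pixel_size_mm = 0.005) {
  p <- list(
    noise_percentile = noise_percentile,
    shadow_intensity_percentile = shadow_intensity_percentile,
    shadow_threshold_scale = shadow_threshold_scale,
    sliding_shadow_size = sliding_shadow_size,
    slope_threshold = slope_threshold,
    gaussian_sigma = gaussian_sigma,
    edge_response_threshold = edge_response_threshold,
    edge_length_threshold = edge_length_threshold,
    clustering_distance_threshold = clustering_distance_threshold,
    guide_wire_distance_threshold = guide_wire_distance_threshold,
    acceptance_distance = acceptance_distance,
    line_row_fraction = line_row_fraction,
    catheter_search_fraction = catheter_search_fraction,
    non_bright_depth_back = non_bright_depth_back,
    non_bright_depth_fwd = non_bright_depth_fwd,
    min_non_bright_pixels = min_non_bright_pixels,
    min_track_fraction = min_track_fraction,
    guide_wire_max_gap = guide_wire_max_gap,
    segment_min_count = segment_min_count,
    segment_smooth_window = segment_smooth_window,
    pixel_size_mm = pixel_size_mm
  )
  class(p) <- "detection_parameters"
  validate_parameters(p)
  p
}

#' Validate a detection parameter set
#'
#' @param p A `"detection_parameters"` list.
#' @return `p`, invisibly, or an error describing the violated constraint.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "detection_parameters"))
  frac <- c("noise_percentile", "shadow_intensity_percentile",
            "line_row_fraction", "catheter_search_fraction",
            "min_track_fraction")
  for (f in frac) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1)
      stop(sprintf("parameter '%s' must be a fraction in (0, 1]", f))
  }
  pospix <- c("sliding_shadow_size", "gaussian_sigma", "edge_length_threshold",
              "clustering_distance_threshold", "guide_wire_distance_threshold",
              "acceptance_distance", "segment_smooth_window")
  for (f in pospix) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop(sprintf("parameter '%s' must be a positive number of pixels", f))
  }
  if (!is.numeric(p$slope_threshold) || p$slope_threshold >= 0)
    stop("parameter 'slope_threshold' must be negative (steep falling slope)")
  if (p$noise_percentile >= 1 || p$shadow_intensity_percentile >= 1)
    stop("percentile parameters must be strictly below 1")
  invisible(p)
}

#' Scale pixel-valued parameters to a different frame geometry
#'
#' The published pixel thresholds refer to 504 x 960 polar frames. For
#' smaller frames (e.g. synthetic phantoms at 128 x 256) the depth-axis
#' thresholds are scaled by the depth ratio, with small floors so that
#' discrete windows stay usable.
#'
#' @param p A `"detection_parameters"` set (defaults if missing).
#' @param n_alines,n_depth Target frame geometry.
#' @param ref_alines,ref_depth Geometry the parameter set refers to.
#' @return A rescaled `"detection_parameters"` list.
#' @export
scale_parameters <- function(p = detection_parameters(),
                             n_alines, n_depth,
                             ref_alines = 504, ref_depth = 960) {
  rd <- n_depth / ref_depth
  p$sliding_shadow_size <- max(3, round(p$sliding_shadow_size * rd))
  p$edge_length_threshold <- max(5, round(p$edge_length_threshold * rd))
  p$guide_wire_distance_threshold <-
    max(5, round(p$guide_wire_distance_threshold * rd))
  p$acceptance_distance <- max(2, round(p$acceptance_distance * rd))
  p$clustering_distance_threshold <-
    max(3, round(p$clustering_distance_threshold * rd))
  p$non_bright_depth_back <- max(3, round(p$non_bright_depth_back * rd))
  p$non_bright_depth_fwd <- max(5, round(p$non_bright_depth_fwd * rd))
  validate_parameters(p)
  p
}

#' Read detection parameters from a YAML config file
#'
#' The file holds a flat mapping of parameter names to values; unknown keys
#' are an error, missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @param base Parameter set supplying defaults.
#' @return A `"detection_parameters"` list.
#' @export
read_config <- function(path, base = detection_parameters()) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) return(base)
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown))
    stop("unknown parameter(s) in config: ", paste(unknown, collapse = ", "))
  for (k in names(cfg)) {
    if (is.null(cfg[[k]])) base[k] <- list(NULL) else base[[k]] <- cfg[[k]]
  }
  validate_parameters(base)
  base
}

#' Write detection parameters to a YAML config file
#'
#' @param p A `"detection_parameters"` list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(p, path) {
  validate_parameters(p)
  yaml::write_yaml(unclass(p), path)
  invisible(path)
}

#' @export
print.detection_parameters <- function(x, ...) {
  cat("Strut detection parameters:\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-30s %s\n", k, if (is.null(v)) "auto (Otsu)" else format(v)))
  }
  invisible(x)
}
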