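#' Detect struts in a single polar frame
#'
#' Runs the per-frame stages on a noise-floored, ROI-masked frame:
#' candidate pixel detection, Gaussian smoothing, compass edge detection
#' of the trailing shadows, edge-guided single-linkage clustering with
#' selection of the first cluster below each top edge / above each bottom
#' edge, and non-bright strut recovery in empty shadow intervals.
#'
#' @param frame Integer matrix `[aline, depth]`, noise-floored.
#' @param roi A `"roi_boundary"`.
#' @param shadow_threshold Maximum shadow intensity for this pullback.
#' @param params A `"detection_parameters"` set.
#' @param frame_index Frame number recorded on the emitted records.
#' @return A list with `struts` (strut records of this frame) and
#'   `counts` (named integer vector of per-stage tallies).
#' @export
detect_frame <- function(frame, roi, shadow_threshold, params,
                         frame_index = 1L) {
  n_alines <- nrow(frame)
  frame <- apply_roi(frame, roi)
  cands <- detect_candidates(frame, roi, shadow_threshold,
                             params$slope_threshold,
                             params$sliding_shadow_size)
  sm <- smooth_frame(frame, params$gaussian_sigma)
  resp_top <- compass_response(sm, "top")
  tops <- extract_edges(resp_top, params$edge_response_threshold,
                        params$edge_length_threshold, "top")
  bottoms <- extract_edges(-resp_top, params$edge_response_threshold,
                           params$edge_length_threshold, "bottom")
  intervals <- pair_edges(tops, bottoms, n_alines)
  clusters <- agglomerate(cands, params$clustering_distance_threshold,
                          n_alines)
  sel <- select_clusters(clusters, intervals, n_alines)
  kept <- clusters[sel$selected]
  recovered <- list()
  for (i in seq_len(nrow(intervals))) {
    if (!is.na(sel$interval_cluster[i])) next
    rec <- recover_non_bright(frame, intervals[i, ], shadow_threshold,
                              n_alines,
                              depth_back = params$non_bright_depth_back,
                              depth_fwd = params$non_bright_depth_fwd,
                              min_pixels = params$min_non_bright_pixels)
    if (!is.null(rec)) recovered[[length(recovered) + 1L]] <- rec
  }
  all_clusters <- c(kept, recovered)
  struts <- if (length(all_clusters)) {
    do.call(rbind, lapply(all_clusters, cluster_to_strut,
                          n_alines = n_alines, frame_index = frame_index))
  } else empty_strut_df()
  list(struts = struts,
       counts = c(candidates = nrow(cands), top_edges = nrow(tops),
                  bottom_edges = nrow(bottoms), clusters = length(clusters),
                  selected = length(sel$selected),
                  recovered = length(recovered)))
}

#' Detect stent struts in a whole pullback
#'
#' The full pipeline, in fixed stage order: (1) preprocessing — global
#' noise floor and catheter-artifact ROI; (2) per-A-line candidate pixel
#' detection; (3) trailing-shadow edge detection; (4) edge-guided
#' clustering with non-bright strut recovery; (5) 3D false-positive
#' removal — guide-wire continuity filter, then stented-segment
#' extraction. The pipeline is fully deterministic. Removed detections are
#' flagged, never deleted, so the audit trail is reconstructible.
#'
#' @param pullback An `"oct_pullback"`.
#' @param params A `"detection_parameters"` set; for non-clinical frame
#'   sizes pass a [scale_parameters()] result.
#' @param guide_wire_filter,segment_filter Enable the two false-positive
#'   removal stages.
#' @param verbose Print per-stage progress.
#' @return An object of class `"oct_detection"`: `struts` (records with
#'   `kind` flags), `noise_floor`, `roi`, `shadow_threshold`,
#'   `guide_wire_track`, `segment`, `frame_counts` (per-frame stage
#'   tallies) and the effective `params`.
#' @export
detect_struts <- function(pullback, params = detection_parameters(),
                          guide_wire_filter = TRUE, segment_filter = TRUE,
                          verbose = FALSE) {
  stopifnot(inherits(pullback, "oct_pullback"))
  validate_parameters(params)
  say <- function(...) if (verbose) message(sprintf(...))

  t0 <- compute_noise_floor(pullback, params$noise_percentile)
  pb <- apply_noise_floor(pullback, t0)
  roi <- compute_catheter_boundary(pb, t0, params$line_row_fraction,
                                   params$catheter_search_fraction)
  say("preprocess: noise floor %d, ROI from depth column %d",
      t0, roi$first_column)
  shadow_thr <- compute_shadow_intensity_threshold(
    pb, roi, params$shadow_intensity_percentile) *
    params$shadow_threshold_scale
  say("candidate detection: shadow intensity threshold %.1f", shadow_thr)

  per_frame <- vector("list", pb$n_frames)
  counts <- vector("list", pb$n_frames)
  for (f in seq_len(pb$n_frames)) {
    res <- detect_frame(get_frame(pb, f), roi, shadow_thr, params,
                        frame_index = f)
    per_frame[[f]] <- res$struts
    counts[[f]] <- res$counts
  }
  struts <- do.call(rbind, per_frame)
  if (is.null(struts)) struts <- empty_strut_df()
  frame_counts <- as.data.frame(do.call(rbind, counts))
  frame_counts$frame <- seq_len(pb$n_frames)
  say("clustering: %d strut candidates over %d frames",
      nrow(struts), pb$n_frames)

  track <- NULL
  if (guide_wire_filter) {
    track <- detect_guide_wire(struts, pb$n_frames, pb$n_alines,
                               params$guide_wire_distance_threshold,
                               params$min_track_fraction,
                               params$guide_wire_max_gap)
    struts <- remove_guide_wire(struts, track, pb$n_alines,
                                params$acceptance_distance)
    say("guide wire: %s",
        if (is.null(track)) "not present" else
          sprintf("track over %d frames", nrow(track)))
  }
  segment <- NULL
  if (segment_filter) {
    seg <- detect_stented_segment(struts, pb$n_frames,
                                  params$segment_min_count,
                                  params$segment_smooth_window)
    segment <- seg$segment
    struts <- seg$struts
    say("stented segment: %s",
        if (is.null(segment)) "none" else
          sprintf("frames %d-%d", segment[1], segment[2]))
  }
  rownames(struts) <- NULL
  structure(list(struts = struts, noise_floor = t0, roi = roi,
                 shadow_threshold = shadow_thr,
                 guide_wire_track = track, segment = segment,
                 frame_counts = frame_counts, params = params,
                 n_frames = pb$n_frames, n_alines = pb$n_alines,
                 n_depth = pb$n_depth),
            class = "oct_detection")
}

#' Active struts of a detection result
#'
#' @param detection An `"oct_detection"`.
#' @return Strut records with `kind` `bright` or `non_bright` (the
#'   detections that survived false-positive removal).
#' @export
active_struts <- function(detection) {
  s <- detection$struts
  s[s$kind %in% c("bright", "non_bright"), , drop = FALSE]
}

#' @export
print.oct_detection <- function(x, ...) {
  act <- sum(x$struts$kind %in% c("bright", "non_bright"))
  cat(sprintf("Strut detection over %d frame(s): %d strut(s)\n",
              x$n_frames, act))
  cat(sprintf("  noise floor %d; ROI from column %d; shadow threshold %.1f\n",
              x$noise_floor, x$roi$first_column, x$shadow_threshold))
  cat(sprintf("  guide wire: %s; stented segment: %s\n",
              if (is.null(x$guide_wire_track)) "absent" else
                sprintf("%d frames flagged",
                        sum(x$struts$kind == "guide_wire_removed")),
              if (is.null(x$segment)) "none" else
                sprintf("frames %d-%d", x$segment[1], x$segment[2])))
  invisible(x)
}

#' Run detection on a pullback file and write results
#'
#' @param input Pullback path (TIFF stack or raw binary + sidecar).
#' @param output_dir Output directory (created if missing).
#' @param params `"detection_parameters"`; `scale_to_input = TRUE` rescales
#'   pixel thresholds from the clinical 504 x 960 geometry to the input's.
#' @param scale_to_input Rescale pixel-valued parameters to the input
#'   frame size.
#' @param guide_wire_filter,segment_filter,verbose See [detect_struts()].
#' @return The `"oct_detection"`, invisibly. Writes `detections.csv`,
#'   `detections.json` and `run_log.yaml` into `output_dir`.
#' @export
run_detect <- function(input, output_dir, params = detection_parameters(),
                       scale_to_input = FALSE, guide_wire_filter = TRUE,
                       segment_filter = TRUE, verbose = TRUE) {
  pb <- read_pullback(input)
  if (scale_to_input)
    params <- scale_parameters(params, pb$n_alines, pb$n_depth)
  det <- detect_struts(pb, params, guide_wire_filter = guide_wire_filter,
                       segment_filter = segment_filter, verbose = verbose)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_detections(det$struts, file.path(output_dir, "detections.csv"),
                   json = file.path(output_dir, "detections.json"))
  log <- list(
    input = input,
    frames = det$n_frames, alines = det$n_alines, depth = det$n_depth,
    noise_floor = det$noise_floor,
    roi_first_column = det$roi$first_column,
    shadow_intensity_threshold = det$shadow_threshold,
    parameters = unclass(det$params),
    stage_totals = as.list(colSums(
      det$frame_counts[, setdiff(names(det$frame_counts), "frame")])),
    guide_wire_frames = if (is.null(det$guide_wire_track)) 0L else
      nrow(det$guide_wire_track),
    stented_segment = if (is.null(det$segment)) "none" else
      as.list(stats::setNames(det$segment, c("first_frame", "last_frame"))),
    n_struts = sum(det$struts$kind %in% c("bright", "non_bright")))
  yaml::write_yaml(log, file.path(output_dir, "run_log.yaml"))
  invisible(det)
}

#' Generate a phantom pullback and write it to disk
#'
#' @param spec A `"phantom_spec"` or path to a YAML spec file.
#' @param output_dir Output directory. Writes `pullback.tif` (16-bit
#'   multipage), `truth.csv` and, when present, `guide_wire_truth.csv`.
#' @return The [generate_phantom()] result, invisibly.
#' @export
run_simulate <- function(spec, output_dir) {
  if (is.character(spec)) spec <- read_phantom_spec(spec)
  ph <- generate_phantom(spec)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_pullback(ph$pullback, file.path(output_dir, "pullback.tif"))
  utils::write.csv(ph$truth, file.path(output_dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(ph$guide_wire_truth))
    utils::write.csv(ph$guide_wire_truth,
                     file.path(output_dir, "guide_wire_truth.csv"),
                     row.names = FALSE, quote = FALSE)
  invisible(ph)
}

#' Evaluate a detections file against a reference file
#'
#' @param detections,truth CSV paths readable by [read_annotations()].
#' @param output_dir Output directory for `report.json` and
#'   `per_status.csv` (when the reference has a `status` column).
#' @param acceptance_distance Matching tolerance in pixels.
#' @param n_alines Number of A-lines per frame.
#' @return The `"strut_evaluation"` report, invisibly.
#' @export
run_evaluate <- function(detections, truth, output_dir,
                         acceptance_distance = 10, n_alines = 504) {
  det <- read_annotations(detections)
  tr <- utils::read.csv(truth, stringsAsFactors = FALSE)
  rep <- evaluate_detections(det, tr, acceptance_distance, n_alines)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- unclass(rep)
  by_status <- out$by_status
  out$by_status <- NULL
  jsonlite::write_json(out, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(by_status))
    utils::write.csv(by_status, file.path(output_dir, "per_status.csv"),
                     row.names = FALSE)
  invisible(rep)
}
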