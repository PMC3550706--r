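#' Match detections to reference struts
#'
#' Per frame, detections and reference (ground-truth or expert) struts are
#' paired one-to-one by an optimal assignment minimizing the total
#' wrap-aware Euclidean distance; only pairs within the acceptance
#' distance count as matches. Optimal (rather than greedy) assignment is
#' order-independent and reproducible. Each reference strut and each
#' detection is used at most once.
#'
#' @param detected,truth Strut record `data.frame`s (columns `frame`,
#'   `aline`, `depth`); rows of `detected` with inactive kinds
#'   (`guide_wire_removed`, `outside_segment_removed`) are ignored.
#' @param acceptance_distance Matching tolerance in pixels.
#' @param n_alines Number of A-lines per frame.
#' @return A list with `pairs` (`data.frame`: `frame`, `truth_row`,
#'   `det_row` — row indices into the inputs — and `distance`),
#'   `unmatched_truth` and `unmatched_detected` (row index vectors), and
#'   `n_detected` (number of active detections considered).
#' @export
match_detections <- function(detected, truth, acceptance_distance,
                             n_alines) {
  det_idx <- seq_len(nrow(detected))
  if (!is.null(detected$kind))
    det_idx <- det_idx[detected$kind %in% c("bright", "non_bright")]
  pairs <- list()
  matched_t <- integer(0); matched_d <- integer(0)
  frames <- union(unique(truth$frame), unique(detected$frame[det_idx]))
  BIG <- 1e9
  for (f in frames) {
    ti <- which(truth$frame == f)
    di <- det_idx[detected$frame[det_idx] == f]
    if (!length(ti) || !length(di)) next
    cost <- outer(seq_along(ti), seq_along(di), function(a, b)
      pixel_dist(truth$aline[ti[a]], truth$depth[ti[a]],
                 detected$aline[di[b]], detected$depth[di[b]], n_alines))
    feasible <- cost <= acceptance_distance
    cost[!feasible] <- BIG
    flip <- nrow(cost) > ncol(cost)
    asg <- if (flip) hungarian_assign(t(cost)) else hungarian_assign(cost)
    for (k in seq_along(asg)) {
      a <- if (flip) asg[k] else k
      b <- if (flip) k else asg[k]
      if (b == 0L || a == 0L || !feasible[a, b]) next
      pairs[[length(pairs) + 1L]] <- data.frame(
        frame = f, truth_row = ti[a], det_row = di[b],
        distance = cost[a, b])
      matched_t <- c(matched_t, ti[a])
      matched_d <- c(matched_d, di[b])
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(frame = integer(0), truth_row = integer(0),
               det_row = integer(0), distance = numeric(0))
  list(pairs = pairs,
       unmatched_truth = setdiff(seq_len(nrow(truth)), matched_t),
       unmatched_detected = setdiff(det_idx, matched_d),
       n_detected = length(det_idx))
}

#' Summarize a matching into an evaluation report
#'
#' Sensitivity is the number of true positives over the number of
#' reference struts; the false-positive ratio is the number of unmatched
#' detections over the number of reference struts. Distance statistics are
#' computed over matched pairs only.
#'
#' @param matching Result of [match_detections()].
#' @param truth Reference strut records; an optional `status` column
#'   yields a per-category breakdown.
#' @param pixel_size_mm Optional mm-per-pixel scale for mm distances.
#' @return A list of class `"strut_evaluation"`.
#' @export
summarize_evaluation <- function(matching, truth, pixel_size_mm = NULL) {
  n_truth <- nrow(truth)
  n_tp <- nrow(matching$pairs)
  n_fp <- length(matching$unmatched_detected)
  dists <- matching$pairs$distance
  rep <- list(
    n_truth = n_truth,
    n_detected = matching$n_detected,
    n_true_positive = n_tp,
    n_false_positive = n_fp,
    sensitivity = if (n_truth > 0) n_tp / n_truth else 0,
    fp_ratio = if (n_truth > 0) n_fp / n_truth else 0,
    distance_mean_px = if (n_tp > 0) mean(dists) else NA_real_,
    distance_sd_px = if (n_tp > 1) stats::sd(dists) else NA_real_)
  if (!is.null(pixel_size_mm) && n_tp > 0)
    rep$distance_mean_mm <- rep$distance_mean_px * pixel_size_mm
  if (!is.null(truth$status) && n_truth > 0) {
    matched <- rep(FALSE, n_truth)
    matched[matching$pairs$truth_row] <- TRUE
    by <- split(matched, truth$status)
    rep$by_status <- data.frame(
      status = names(by),
      n_truth = vapply(by, length, integer(1)),
      n_true_positive = vapply(by, sum, numeric(1)),
      sensitivity = vapply(by, mean, numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  class(rep) <- "strut_evaluation"
  rep
}

#' @export
print.strut_evaluation <- function(x, ...) {
  cat(sprintf("Strut detection evaluation: %d reference, %d detected\n",
              x$n_truth, x$n_detected))
  cat(sprintf("  sensitivity %.1f%% (%d TP), FP ratio %.1f%% (%d FP)\n",
              100 * x$sensitivity, x$n_true_positive,
              100 * x$fp_ratio, x$n_false_positive))
  if (!is.na(x$distance_mean_px))
    cat(sprintf("  distance error %.2f +/- %.2f px\n",
                x$distance_mean_px,
                if (is.na(x$distance_sd_px)) 0 else x$distance_sd_px))
  if (!is.null(x$by_status)) {
    cat("  by status:\n")
    for (i in seq_len(nrow(x$by_status)))
      cat(sprintf("    %-12s %.1f%% of %d\n", x$by_status$status[i],
                  100 * x$by_status$sensitivity[i], x$by_status$n_truth[i]))
  }
  invisible(x)
}

#' Evaluate detections against reference struts
#'
#' Convenience wrapper: [match_detections()] followed by
#' [summarize_evaluation()].
#'
#' @inheritParams match_detections
#' @inheritParams summarize_evaluation
#' @return A `"strut_evaluation"` report with the matching attached as
#'   attribute `"matching"`.
#' @export
evaluate_detections <- function(detected, truth, acceptance_distance,
                                n_alines, pixel_size_mm = NULL) {
  m <- match_detections(detected, truth, acceptance_distance, n_alines)
  rep <- summarize_evaluation(m, truth, pixel_size_mm)
  attr(rep, "matching") <- m
  rep
}

#' Inter-observer agreement between two annotation sets
#'
#' Applies the same tolerance-based optimal matching to two independent
#' annotation sets and reports the number of agreements divided by the
#' average number of struts marked by the two observers.
#'
#' @param a,b Strut record `data.frame`s of the two observers.
#' @param acceptance_distance Matching tolerance in pixels.
#' @param n_alines Number of A-lines per frame.
#' @return A list with `agreement`, `n_matches`, `n_a`, `n_b`.
#' @export
interobserver_agreement <- function(a, b, acceptance_distance, n_alines) {
  m <- match_detections(a, b, acceptance_distance, n_alines)
  n_matches <- nrow(m$pairs)
  list(agreement = n_matches / mean(c(nrow(a), nrow(b))),
       n_matches = n_matches, n_a = nrow(b), n_b = nrow(a))
}

#' Parameter sensitivity sweep
#'
#' Reruns the full detection pipeline with each of the five main
#' parameters (maximum shadow intensity threshold, sliding shadow window,
#' slope threshold, shadow edge length threshold, clustering distance
#' threshold) perturbed multiplicatively, and evaluates each run against
#' the ground truth. The shadow intensity threshold is perturbed by
#' scaling the computed threshold value.
#'
#' @param pullback An `"oct_pullback"`.
#' @param truth Reference strut records.
#' @param params Baseline `"detection_parameters"`.
#' @param deltas Fractional perturbations (default -20%, 0, +20%).
#' @param ... Passed to [detect_struts()] (e.g. `guide_wire_filter`).
#' @return A `data.frame` with one row per (parameter, delta):
#'   `parameter`, `delta`, `sensitivity`, `fp_ratio`, `distance_mean_px`,
#'   `distance_sd_px`, `n_detected`.
#' @export
parameter_sweep <- function(pullback, truth, params = detection_parameters(),
                            deltas = c(-0.2, 0, 0.2), ...) {
  swept <- c("shadow_threshold_scale", "sliding_shadow_size",
             "slope_threshold", "edge_length_threshold",
             "clustering_distance_threshold")
  labels <- c("max_shadow_intensity_threshold", "sliding_shadow_size",
              "slope_threshold", "shadow_edge_length_threshold",
              "clustering_distance_threshold")
  rows <- list()
  for (k in seq_along(swept)) {
    for (d in deltas) {
      p <- params
      p[[swept[k]]] <- params[[swept[k]]] * (1 + d)
      det <- detect_struts(pullback, p, ...)
      ev <- evaluate_detections(det$struts, truth,
                                params$acceptance_distance,
                                pullback$n_alines)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = labels[k], delta = d,
        sensitivity = ev$sensitivity, fp_ratio = ev$fp_ratio,
        distance_mean_px = ev$distance_mean_px,
        distance_sd_px = ev$distance_sd_px,
        n_detected = ev$n_detected, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
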