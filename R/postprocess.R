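#' Detect the guide wire track across a pullback
#'
#' The guide wire reflects like a strut but, unlike any strut, it is
#' closer to the imaging catheter than everything else and its position is
#' continuous throughout the pullback. Per frame the detection closest to
#' the catheter (minimal depth) is taken; entries of nearby frames (at
#' most `max_gap` frames apart, so a single frame in which the wire was
#' missed does not sever the track) are chained when they lie within the
#' guide-wire distance threshold (wrap-aware Euclidean pixels). The
#' longest chain is accepted as the guide wire only when its entries
#' cover at least `min_track_fraction` of the frames; otherwise no guide
#' wire is reported.
#'
#' @param struts Strut record `data.frame` over all frames (active kinds
#'   `bright`/`non_bright` are considered).
#' @param n_frames,n_alines Pullback geometry.
#' @param distance_threshold Maximum frame-to-frame displacement in pixels.
#' @param min_track_fraction Minimum fraction of frames the chain must
#'   cover.
#' @param max_gap Maximum number of frames a chain link may bridge.
#' @return A `data.frame` track with columns `frame`, `aline`, `depth`, or
#'   `NULL` when no guide wire is present.
#' @export
detect_guide_wire <- function(struts, n_frames, n_alines,
                              distance_threshold = 40,
                              min_track_fraction = 0.8,
                              max_gap = 2) {
  if (n_frames < 2L) return(NULL)
  active <- struts[struts$kind %in% c("bright", "non_bright"), , drop = FALSE]
  if (nrow(active) == 0L) return(NULL)
  entry <- matrix(NA_real_, nrow = n_frames, ncol = 2)  # aline, depth
  for (f in unique(active$frame)) {
    rows <- active[active$frame == f, , drop = FALSE]
    i <- which.min(rows$depth)
    entry[f, ] <- c(rows$aline[i], rows$depth[i])
  }
  fs <- which(!is.na(entry[, 1]))
  if (length(fs) < 2L) return(NULL)
  # longest chain of entries linked across at most max_gap frames; an
  # entry that breaks continuity (a frame where the wire was missed and
  # a strut is closest instead) can be skipped by the link bridging it
  best_len <- rep(1L, n_frames)   # chain length ending at frame f
  prev <- rep(NA_integer_, n_frames)
  for (f in fs) {
    for (g in fs[fs < f & fs >= f - max_gap]) {
      d <- pixel_dist(entry[g, 1], entry[g, 2],
                      entry[f, 1], entry[f, 2], n_alines)
      if (d <= distance_threshold && best_len[g] + 1L > best_len[f]) {
        best_len[f] <- best_len[g] + 1L
        prev[f] <- g
      }
    }
  }
  end <- which.max(best_len)
  if (best_len[end] / n_frames < min_track_fraction) return(NULL)
  chain <- integer(0)
  f <- end
  while (!is.na(f)) {
    chain <- c(f, chain)
    f <- prev[f]
  }
  data.frame(frame = chain,
             aline = entry[chain, 1],
             depth = entry[chain, 2])
}

#' Flag guide-wire detections
#'
#' In each frame of the track the single detection nearest to the track
#' entry (within the acceptance distance) is re-flagged
#' `guide_wire_removed`. Flagged records stay in the output for audit but
#' are excluded from strut counts and evaluation.
#'
#' @param struts Strut record `data.frame`.
#' @param track Guide-wire track from [detect_guide_wire()] (`NULL` is a
#'   no-op).
#' @param n_alines Number of A-lines per frame.
#' @param acceptance_distance Association tolerance in pixels.
#' @return The strut records with updated `kind`.
#' @export
remove_guide_wire <- function(struts, track, n_alines,
                              acceptance_distance = 10) {
  if (is.null(track) || nrow(struts) == 0L) return(struts)
  for (k in seq_len(nrow(track))) {
    f <- track$frame[k]
    idx <- which(struts$frame == f &
                 struts$kind %in% c("bright", "non_bright"))
    if (!length(idx)) next
    d <- pixel_dist(struts$aline[idx], struts$depth[idx],
                    track$aline[k], track$depth[k], n_alines)
    if (min(d) <= acceptance_distance)
      struts$kind[idx[which.min(d)]] <- "guide_wire_removed"
  }
  struts
}

#' Detect the stented frame segment
#'
#' Pullbacks are longer than the stent; frames before and after it contain
#' no true struts, only occasional false candidates. The per-frame counts
#' of active detections are smoothed with a centered moving average and the
#' longest contiguous run of frames whose smoothed count reaches
#' `segment_min_count` is taken as the stented segment. Active detections
#' outside it are re-flagged `outside_segment_removed`.
#'
#' @param struts Strut record `data.frame` (guide wire already removed).
#' @param n_frames Number of frames of the pullback.
#' @param segment_min_count Minimum smoothed strut count inside the
#'   segment.
#' @param segment_smooth_window Moving-average window in frames (partial
#'   windows at the pullback ends).
#' @return A list with `segment` (`c(first, last)` or `NULL` when no frame
#'   qualifies) and `struts` (records with updated `kind`).
#' @export
detect_stented_segment <- function(struts, n_frames,
                                   segment_min_count = 3,
                                   segment_smooth_window = 5) {
  active <- struts$kind %in% c("bright", "non_bright")
  counts <- tabulate(struts$frame[active], nbins = n_frames)
  half <- floor(segment_smooth_window / 2)
  cs <- cumsum(c(0, counts))
  smoothed <- vapply(seq_len(n_frames), function(f) {
    lo <- max(1L, f - half); hi <- min(n_frames, f + half)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }, numeric(1))
  ok <- smoothed >= segment_min_count
  if (!any(ok)) {
    struts$kind[active] <- "outside_segment_removed"
    return(list(segment = NULL, struts = struts))
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  segment <- c(starts[best], ends[best])
  outside <- active & (struts$frame < segment[1] | struts$frame > segment[2])
  struts$kind[outside] <- "outside_segment_removed"
  list(segment = segment, struts = struts)
}
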