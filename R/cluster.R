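#' Agglomerate candidate pixels into clusters
#'
#' Starting from singleton clusters, clusters merge while the minimal
#' distance between any two of their members is strictly below the merge
#' threshold (single linkage). Distance is Euclidean on (row, depth) pixels
#' with the row difference wrap-aware, so candidates split across the
#' frame seam still merge. The result is the connected-component partition
#' of the "closer than threshold" graph and hence independent of input
#' order.
#'
#' @param candidates Candidate `data.frame` from [detect_candidates()].
#' @param merge_distance Merge threshold in pixels (merging requires
#'   distance strictly below it).
#' @param n_alines Number of A-lines per frame.
#' @return A list of clusters; each is a list with `members` (rows of
#'   `candidates`), `centroid_aline` (wrap-aware circular mean),
#'   `centroid_depth` and `kind = "bright"`.
#' @export
agglomerate <- function(candidates, merge_distance, n_alines) {
  n <- nrow(candidates)
  if (n == 0L) return(list())
  parent <- uf_new(n)
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      d <- pixel_dist(candidates$aline[i], candidates$peak_depth[i],
                      candidates$aline[(i + 1L):n],
                      candidates$peak_depth[(i + 1L):n], n_alines)
      for (j in which(d < merge_distance))
        parent <- uf_union(parent, i, i + j)
    }
  }
  labels <- uf_labels(parent)
  lapply(split(seq_len(n), labels), function(idx) {
    m <- candidates[idx, , drop = FALSE]
    list(members = m,
         centroid_aline = circular_mean_row(m$aline, n_alines),
         centroid_depth = mean(m$peak_depth),
         kind = "bright")
  })
}

#' Select true strut clusters using the shadow edges
#'
#' A strut sits immediately below its shadow's top edge and immediately
#' above the bottom edge. For each top edge the first cluster below it (in
#' wrap-aware angular order) is kept; for each bottom edge the first
#' cluster above it. Every other cluster is discarded as a false positive.
#' A cluster chosen by both edges of its interval counts once.
#'
#' @param clusters Cluster list from [agglomerate()].
#' @param intervals Interval `data.frame` from [pair_edges()].
#' @param n_alines Number of A-lines per frame.
#' @return A list with `selected` (indices into `clusters`) and
#'   `interval_cluster` (for each interval row, the index of a selected
#'   cluster lying inside its span, or `NA`).
#' @export
select_clusters <- function(clusters, intervals, n_alines) {
  ni <- nrow(intervals)
  if (!length(clusters) || ni == 0L)
    return(list(selected = integer(0), interval_cluster = rep(NA_integer_, ni)))
  cent <- vapply(clusters, function(cl) cl$centroid_aline, numeric(1))
  selected <- integer(0)
  for (i in seq_len(ni)) {
    t_row <- intervals$top_aline[i]
    b_row <- intervals$bottom_aline[i]
    if (!is.na(t_row)) {
      fd <- forward_row_dist(t_row, cent, n_alines)
      selected <- c(selected, which.min(fd))
    }
    if (!is.na(b_row)) {
      bd <- forward_row_dist(cent, b_row, n_alines)
      selected <- c(selected, which.min(bd))
    }
  }
  selected <- sort(unique(selected))
  interval_cluster <- rep(NA_integer_, ni)
  for (i in seq_len(ni)) {
    t_row <- intervals$top_aline[i]
    b_row <- intervals$bottom_aline[i]
    if (is.na(t_row) || is.na(b_row)) next
    inside <- selected[vapply(selected, function(s)
      interval_contains(t_row, b_row, cent[s], n_alines), logical(1))]
    if (length(inside)) interval_cluster[i] <- inside[1L]
  }
  list(selected = selected, interval_cluster = interval_cluster)
}

#' Recover a non-bright strut inside an empty shadow interval
#'
#' Struts far from the catheter or under thick tissue coverage may be too
#' dim for the slope-based candidate detection while still casting a clear
#' shadow. When a pair of top/bottom edges encloses no selected cluster,
#' the rows between the edges are searched in a depth window anchored at
#' the edges' start columns; the brightest pixel of each row that exceeds
#' the maximum shadow intensity threshold joins a cluster flagged
#' `non_bright`.
#'
#' @param frame Integer matrix `[aline, depth]` (noise-floored, ROI
#'   masked).
#' @param interval One row of the [pair_edges()] table; both edges must be
#'   present.
#' @param shadow_threshold Maximum shadow intensity.
#' @param n_alines Number of A-lines per frame.
#' @param depth_back,depth_fwd Search window extent before/after the
#'   earlier edge start column.
#' @param min_pixels Minimum number of supra-threshold pixels.
#' @return A cluster (as in [agglomerate()], `kind = "non_bright"`) or
#'   `NULL`.
#' @export
recover_non_bright <- function(frame, interval, shadow_threshold, n_alines,
                               depth_back = 10, depth_fwd = 30,
                               min_pixels = 2) {
  t_row <- interval$top_aline
  b_row <- interval$bottom_aline
  if (is.na(t_row) || is.na(b_row)) return(NULL)
  span <- forward_row_dist(t_row, b_row, n_alines)
  rows <- ((t_row - 1L + 0:span) %% n_alines) + 1L
  if (length(rows) >= 3L) rows <- rows[-c(1L, length(rows))]  # shadow interior
  anchor <- min(interval$top_start, interval$bottom_start)
  cols <- max(1L, anchor - depth_back):min(ncol(frame), anchor + depth_fwd)
  hits <- lapply(rows, function(a) {
    v <- frame[a, cols]
    j <- which.max(v)
    if (v[j] > shadow_threshold)
      data.frame(aline = a, peak_depth = cols[j],
                 peak_intensity = as.numeric(v[j]),
                 shadow_start = NA_integer_, dist = NA_integer_,
                 slope = NA_real_)
    else NULL
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (length(hits) < min_pixels) return(NULL)
  m <- do.call(rbind, hits)
  list(members = m,
       centroid_aline = circular_mean_row(m$aline, n_alines),
       centroid_depth = mean(m$peak_depth),
       kind = "non_bright")
}

#' Convert a cluster to a strut record
#'
#' The strut position is the average position of the cluster members: the
#' wrap-aware circular mean of their rows and the arithmetic mean of their
#' peak depths, each rounded to the nearest pixel (ties to even). This
#' approximates the middle point of the strut front edge.
#'
#' @param cluster A cluster from [agglomerate()] or [recover_non_bright()].
#' @param n_alines Number of A-lines per frame.
#' @param frame_index Frame the cluster belongs to.
#' @return A one-row strut record `data.frame`.
#' @export
cluster_to_strut <- function(cluster, n_alines, frame_index = NA_integer_) {
  a <- round(cluster$centroid_aline)
  a <- ((a - 1L) %% n_alines) + 1L
  strut_records(frame = frame_index, aline = a,
                depth = round(cluster$centroid_depth), kind = cluster$kind)
}
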