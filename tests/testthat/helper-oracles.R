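# Independent brute-force oracles used to pin the fast implementations.

# Order statistic at rank ceiling(p * N) by full sort.
oracle_percentile <- function(x, p) {
  sort(as.vector(x))[ceiling(p * length(x))]
}

# Exhaustive O(n * w) sliding-window shadow search along one intensity row.
oracle_shadow_start <- function(v, from_depth, threshold, window) {
  n <- length(v)
  half <- ceiling(window / 2)
  for (d in seq(from_depth + 1, n)) {
    if (d > n) break
    w_end <- min(d + window - 1, n)
    len <- w_end - d + 1
    full <- len == window
    truncated_ok <- w_end == n && len >= half
    if ((full || truncated_ok) && all(v[d:w_end] <= threshold)) return(d)
  }
  NULL
}

# Single-linkage partition via repeated scanning over an explicit
# wrap-aware distance matrix: merge any two clusters whose minimum
# inter-member distance is strictly below the threshold, until stable.
oracle_single_linkage <- function(aline, depth, threshold, n_alines) {
  n <- length(aline)
  lab <- seq_len(n)
  dmat <- outer(seq_len(n), seq_len(n), function(i, j)
    pixel_dist(aline[i], depth[i], aline[j], depth[j], n_alines))
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (lab[i] != lab[j] && dmat[i, j] < threshold) {
        lab[lab == lab[j]] <- lab[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# Exhaustive optimal assignment (all permutations) for small matching
# problems; returns the minimal total distance over pairings within the
# acceptance distance, maximizing the number of matches first.
oracle_assignment <- function(cost, acceptance) {
  if (nrow(cost) > ncol(cost)) cost <- t(cost)
  n <- nrow(cost); m <- ncol(cost)
  idx <- seq_len(m)
  best <- c(-1, Inf)  # (n_matches, total_distance)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  for (p in perms(idx)) {
    matched <- 0; total <- 0
    for (i in seq_len(min(n, m))) {
      d <- cost[i, p[i]]
      if (d <= acceptance) { matched <- matched + 1; total <- total + d }
    }
    if (matched > best[1] || (matched == best[1] && total < best[2]))
      best <- c(matched, total)
  }
  list(n_matches = best[1], total = best[2])
}

# Partition equality up to label renaming.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}
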