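cand_df <- function(aline, depth) {
  data.frame(aline = aline, peak_depth = depth,
             peak_intensity = 1000, shadow_start = depth + 5,
             dist = 5, slope = -500)
}

test_that("agglomeration chains candidates under the merge threshold", {
  cl <- agglomerate(cand_df(c(10, 12, 14), c(50, 50, 50)), 4, 128)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$centroid_aline, 12)

  cl <- agglomerate(cand_df(c(10, 20), c(50, 50)), 4, 128)
  expect_length(cl, 2)

  # merging is strict: distance exactly at the threshold does not merge
  cl <- agglomerate(cand_df(c(10, 14), c(50, 50)), 4, 128)
  expect_length(cl, 2)

  # wrap case: rows 2 and 503 are 3 apart on a 504-row frame
  cl <- agglomerate(cand_df(c(2, 503), c(50, 50)), 4, 504)
  expect_length(cl, 1)
})

test_that("agglomeration matches a brute-force single-linkage oracle", {
  set.seed(51)
  for (i in 1:60) {
    n <- sample(2:50, 1)
    n_alines <- 64
    # mixed layout incl. points near the wrap seam
    aline <- sample(c(1:8, 30:40, 58:64), n, TRUE)
    depth <- sample(1:80, n, TRUE)
    thr <- sample(c(2, 3, 4, 6), 1)
    cl <- agglomerate(cand_df(aline, depth), thr, n_alines)
    got <- integer(n)
    for (k in seq_along(cl)) {
      idx <- as.integer(rownames(cl[[k]]$members))
      got[idx] <- k
    }
    want <- oracle_single_linkage(aline, depth, thr, n_alines)
    expect_true(same_partition(got, want))
  }
})

test_that("agglomeration is permutation-invariant and idempotent", {
  set.seed(52)
  aline <- sample(1:64, 30, TRUE); depth <- sample(1:80, 30, TRUE)
  cl1 <- agglomerate(cand_df(aline, depth), 4, 64)
  perm <- sample(30)
  cl2 <- agglomerate(cand_df(aline[perm], depth[perm]), 4, 64)
  sig <- function(cl) sort(unname(vapply(cl, function(c)
    paste(sort(paste(c$members$aline, c$members$peak_depth)), collapse = ";"),
    character(1))))
  expect_identical(sig(cl1), sig(cl2))

  # re-clustering the members of one cluster never splits it
  for (c in cl1) {
    again <- agglomerate(c$members, 4, 64)
    expect_length(again, 1)
  }
})

test_that("cluster positions are wrap-aware means rounded to pixels", {
  cl <- agglomerate(cand_df(c(10, 12), c(200, 202)), 4, 504)
  s <- cluster_to_strut(cl[[1]], 504, frame_index = 7)
  expect_equal(s$aline, 11)
  expect_equal(s$depth, 201)
  expect_equal(s$frame, 7)
  expect_equal(s$kind, "bright")

  s1 <- cluster_to_strut(agglomerate(cand_df(5, 40), 4, 504)[[1]], 504)
  expect_equal(c(s1$aline, s1$depth), c(5, 40))

  # members straddling the seam average onto the seam, not mid-frame
  cl <- agglomerate(cand_df(c(503, 3), c(100, 100)), 8, 504)
  s <- cluster_to_strut(cl[[1]], 504)
  expect_equal(s$aline, 1)
  expect_equal(circular_mean_row(c(503, 3), 504), 1)
})

test_that("edge-guided selection keeps the first cluster below/above", {
  iv <- data.frame(top_aline = 100, bottom_aline = 112,
                   top_start = 40, bottom_start = 42, span = 12)
  cl <- agglomerate(cand_df(c(105, 160), c(40, 90)), 4, 504)
  # order clusters by centroid for stable indexing
  cent <- unname(vapply(cl, function(c) c$centroid_aline, numeric(1)))
  sel <- select_clusters(cl, iv, 504)
  expect_equal(sort(cent[sel$selected]), 105)
  expect_equal(cent[sel$interval_cluster[1]], 105)

  # no intervals: every cluster is removed as false
  sel0 <- select_clusters(cl, iv[0, ], 504)
  expect_length(sel0$selected, 0)
})

test_that("non-bright struts are recovered from empty shadow intervals", {
  n_a <- 64; n_d <- 160
  fr <- matrix(15L, n_a, n_d)
  fr[, 1:100] <- 900L            # tissue in front
  rows <- 20:26
  fr[rows, 101:n_d] <- 15L       # trailing shadow
  fr[21:25, 96:99] <- 1200L      # dim blob at 1.2x the shadow threshold
  iv <- data.frame(top_aline = 20, bottom_aline = 26,
                   top_start = 101, bottom_start = 101, span = 6)
  cl <- recover_non_bright(fr, iv, shadow_threshold = 1000, n_alines = n_a,
                           depth_back = 10, depth_fwd = 30, min_pixels = 2)
  expect_false(is.null(cl))
  expect_equal(cl$kind, "non_bright")
  s <- cluster_to_strut(cl, n_a)
  expect_equal(s$aline, 23)
  expect_true(abs(s$depth - 96) <= 2)
  expect_equal(s$kind, "non_bright")

  # pure shadow: nothing above the threshold, nothing recovered
  fr[21:25, 96:99] <- 15L
  expect_null(recover_non_bright(fr, iv, 1000, n_a))
  # one-sided interval: recovery needs both edges
  iv1 <- iv; iv1$bottom_aline <- NA
  expect_null(recover_non_bright(fr, iv1, 1000, n_a))
})
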