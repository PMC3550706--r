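test_that("Gaussian smoothing preserves constants, wraps rows, conserves mass", {
  fr <- matrix(750, 20, 30)
  sm <- smooth_frame(fr, 1.5)
  expect_equal(sm, fr, tolerance = 1e-6)

  # single bright pixel on row 1: wrap makes the response symmetric
  fr <- matrix(0, 16, 16); fr[1, 8] <- 1000
  sm <- smooth_frame(fr, 2)
  for (k in 1:4) expect_equal(sm[1 + k, 8], sm[16 - k + 1, 8], tolerance = 1e-8)

  set.seed(41)
  fr <- matrix(runif(40 * 60, 0, 1000), 40, 60)
  sm <- smooth_frame(fr, 1.5)
  expect_lt(abs(sum(sm) - sum(fr)) / sum(fr), 0.001)
})

test_that("compass kernels respond to the correct step polarity", {
  fr <- matrix(0, 20, 30)
  fr[1:10, ] <- 1000  # rows 1-10 bright, 11-20 dark
  top <- compass_response(fr, "top")
  bottom <- compass_response(fr, "bottom")
  # maximal top response at the bright-to-dark boundary rows
  peak_rows <- which(top == max(top), arr.ind = TRUE)[, 1]
  expect_true(all(peak_rows %in% c(10, 11)))
  expect_true(all(bottom[10:11, ] <= 0))
  # wrap seam rows 20/1 form the dark-to-bright (bottom) edge
  expect_true(all(bottom[c(20, 1), 2:29] > 0))

  expect_true(all(compass_response(matrix(42, 8, 8), "top") == 0))
  # the two kernels are exact negations
  set.seed(42)
  fr <- matrix(runif(30 * 40, 0, 5000), 30, 40)
  expect_equal(compass_response(fr, "top"), -compass_response(fr, "bottom"))
})

test_that("flipping the angular axis exchanges top and bottom responses", {
  set.seed(43)
  fr <- matrix(runif(24 * 30, 0, 5000), 24, 30)
  flipped <- fr[rev(seq_len(nrow(fr))), ]
  top_f <- compass_response(flipped, "top")
  bottom <- compass_response(fr, "bottom")
  expect_equal(top_f, bottom[rev(seq_len(nrow(fr))), ], tolerance = 1e-9)
})

test_that("edge extraction keeps only long edges", {
  toy <- toy_strut_frame(n_depth = 160, front = 30)  # shadow 127 columns
  sm <- smooth_frame(toy$frame, 1.5)
  top <- extract_edges(compass_response(sm, "top"), NULL, 100, "top")
  expect_equal(nrow(top), 1)
  expect_equal(top$kind, "top")
  expect_true(top$aline %in% (min(toy$rows) + c(-1, 0)))
  expect_gte(top$length, 100)

  # a 60-column shadow dies at threshold 100 but survives at 50
  toy2 <- toy_strut_frame(n_depth = 93, front = 30)
  sm2 <- smooth_frame(toy2$frame, 1.5)
  resp2 <- compass_response(sm2, "top")
  expect_equal(nrow(extract_edges(resp2, NULL, 100, "top")), 0)
  expect_equal(nrow(extract_edges(resp2, NULL, 50, "top")), 1)
})

test_that("edge grouping matches an independent component-labelling oracle", {
  set.seed(44)
  for (i in 1:20) {
    resp <- matrix(rnorm(30 * 50, 0, 1), 30, 50)
    thr <- 1.2
    len <- sample(2:6, 1)
    got <- extract_edges(resp, thr, len, "top")

    # oracle: label supra-threshold runs, connect runs on rows <= 1 apart
    # (wrap-aware) with overlapping spans via igraph, keep components
    # whose longest run reaches the length threshold
    runs <- list()
    for (a in seq_len(nrow(resp))) {
      r <- rle(resp[a, ] > thr)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (k in which(r$values))
        runs[[length(runs) + 1]] <- c(a, starts[k], ends[k])
    }
    if (!length(runs)) {
      expect_equal(nrow(got), 0)
      next
    }
    runs <- do.call(rbind, runs)
    n <- nrow(runs)
    adj <- which(outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
      i < j &&
        wrap_row_dist(runs[i, 1], runs[j, 1], nrow(resp)) <= 1 &&
        runs[i, 2] <= runs[j, 3] && runs[j, 2] <= runs[i, 3]
    })), arr.ind = TRUE)
    g <- igraph::graph_from_edgelist(adj, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    longest <- tapply(runs[, 3] - runs[, 2] + 1, comp, max)
    expect_equal(nrow(got), sum(longest >= len))
  }
})

test_that("edge pairing is wrap-aware and tolerates one-sided shadows", {
  mk <- function(kind, aline, start = 40) {
    data.frame(kind = kind, aline = aline, depth_start = start,
               depth_end = start + 150, length = 151)
  }
  iv <- pair_edges(mk("top", 100), mk("bottom", 112), 504)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$span, 12)

  # bottom at row 3 belongs to the top at row 500 across the seam
  iv <- pair_edges(mk("top", 500), mk("bottom", 3), 504)
  expect_equal(iv$top_aline, 500)
  expect_equal(iv$bottom_aline, 3)
  expect_equal(iv$span, 7)

  # unpaired edges become one-sided intervals
  iv <- pair_edges(mk("top", c(10, 200)), mk("bottom", 16), 504)
  expect_equal(nrow(iv), 2)
  expect_true(is.na(iv$bottom_aline[iv$top_aline == 200]))
  iv <- pair_edges(mk("top", 1)[0, ], mk("bottom", 16), 504)
  expect_equal(nrow(iv), 1)
  expect_true(is.na(iv$top_aline))
})

test_that("clean rectangular shadows give exactly one top and bottom edge each", {
  n_a <- 60
  M <- matrix(600, n_a, 160)
  bands <- list(5:9, 25:29, 45:49)
  for (b in bands) for (a in b) M[a, 35:160] <- 15
  sm <- smooth_frame(M, 1.5)
  resp <- compass_response(sm, "top")
  tops <- extract_edges(resp, NULL, 100, "top")
  bottoms <- extract_edges(-resp, NULL, 100, "bottom")
  expect_equal(nrow(tops), length(bands))
  expect_equal(nrow(bottoms), length(bands))
  iv <- pair_edges(tops, bottoms, n_a)
  expect_equal(nrow(iv), 3)
  expect_true(all(iv$span >= 4 & iv$span <= 8))
})
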