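roi_all <- structure(list(first_column = 1L, line_columns = integer(0)),
                     class = "roi_boundary")

test_that("shadow intensity threshold is the ROI order statistic", {
  pb <- oct_pullback(array(500L, dim = c(4, 8, 2)))
  expect_equal(compute_shadow_intensity_threshold(pb, roi_all, 0.89), 500)

  pb <- oct_pullback(array(sample(1:100), dim = c(10, 10, 1)))
  expect_equal(compute_shadow_intensity_threshold(pb, roi_all, 0.89), 89)

  # masking columns changes the histogram the threshold is computed on
  set.seed(31)
  arr <- array(sample(0:4000, 10 * 20 * 2, TRUE), dim = c(10, 20, 2))
  pb <- oct_pullback(arr)
  roi <- structure(list(first_column = 6L, line_columns = 1:5),
                   class = "roi_boundary")
  expect_equal(compute_shadow_intensity_threshold(pb, roi, 0.89),
               oracle_percentile(arr[, 6:20, ], 0.89))
})

test_that("A-line peaks break ties toward the smallest depth", {
  fr <- rbind(c(0L, 0L, 9L, 4L, 9L, 0L))
  pk <- find_aline_peak(fr, 1, roi_all)
  expect_equal(pk$peak_depth, 3)
  expect_equal(pk$peak_intensity, 9)
  expect_null(find_aline_peak(rbind(rep(0L, 6)), 1, roi_all))
  set.seed(32)
  for (i in 1:50) {
    v <- sample(0:50, 30, TRUE)
    fr <- rbind(v)
    pk <- find_aline_peak(fr, 1, roi_all)
    if (all(v == 0)) expect_null(pk)
    else expect_equal(pk$peak_depth, which.max(v))
  }
})

test_that("shadow window search matches the exhaustive oracle", {
  # step profile: bright then dark
  v <- c(rep(1000, 10), rep(0, 110))
  expect_equal(find_shadow_start(rbind(v), 1, 1, 50, 30), 11)
  # everything above threshold: no shadow
  expect_null(find_shadow_start(rbind(rep(1000, 50)), 1, 1, 50, 30))
  # truncated window at the far edge: accepted iff >= window/2 remains
  v <- c(rep(1000, 40), rep(0, 20))
  expect_equal(find_shadow_start(rbind(v), 1, 1, 50, 30), 41)
  v <- c(rep(1000, 50), rep(0, 10))
  expect_null(find_shadow_start(rbind(v), 1, 1, 50, 30))

  set.seed(33)
  for (i in 1:100) {
    v <- sample(0:120, 80, TRUE)
    thr <- sample(20:100, 1)
    w <- sample(3:20, 1)
    from <- sample(1:40, 1)
    got <- find_shadow_start(rbind(v), 1, from, thr, w)
    want <- oracle_shadow_start(v, from, thr, w)
    if (is.null(want)) expect_null(got) else expect_equal(got, want)
  }
})

test_that("candidates require a steep two-point slope to the shadow", {
  n_d <- 260
  fr <- matrix(200L, 2, n_d)
  # kept: peak 5000, shadow value 100 five pixels behind -> slope -980
  fr[1, ] <- c(rep(200L, 20), 5000L, rep(3000L, 4), rep(100L, n_d - 25))
  # rejected: peak 600, shadow 120 at distance 200 -> slope -2.4
  fr[2, ] <- c(rep(500L, 20), 600L, rep(550L, 199), rep(120L, n_d - 220))
  cands <- detect_candidates(fr, roi_all, shadow_threshold = 500,
                             slope_threshold = -48, window = 10)
  expect_equal(cands$aline, 1)
  expect_equal(cands$peak_depth, 21)
  expect_equal(cands$shadow_start, 26)
  expect_equal(cands$slope, (100 - 5000) / 5)

  # a pure-shadow frame yields no candidates
  dark <- matrix(10L, 4, 50)
  expect_equal(nrow(detect_candidates(dark, roi_all, 500, -48, 10)), 0)
})

test_that("at most one candidate per A-line; slopes scale with intensity", {
  toy <- toy_strut_frame()
  cands <- detect_candidates(toy$frame, roi_all, shadow_threshold = 100,
                             slope_threshold = -48, window = 10)
  expect_lte(max(table(cands$aline)), 1)
  expect_true(all(toy$rows %in% cands$aline))
  expect_true(all(cands$peak_depth[cands$aline %in% toy$rows] == toy$front))

  c2 <- detect_candidates(toy$frame * 3L, roi_all, shadow_threshold = 300,
                          slope_threshold = -48 * 3, window = 10)
  expect_equal(c2$aline, cands$aline)
  expect_equal(c2$slope, cands$slope * 3)
})
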