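test_that("matching honours the acceptance distance exactly", {
  truth <- strut_records(1, 100, 200)
  det <- strut_records(1, 100, 200)
  m <- match_detections(det, truth, 10, 504)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$distance, 0)

  det11 <- strut_records(1, 100, 211)  # 11 px away
  m2 <- match_detections(det11, truth, 10, 504)
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(m2$unmatched_truth, 1)
  expect_equal(m2$unmatched_detected, 1)

  det10 <- strut_records(1, 100, 210)  # exactly at the tolerance
  expect_equal(nrow(match_detections(det10, truth, 10, 504)$pairs), 1)

  # matching uses the wrap-aware metric
  m3 <- match_detections(strut_records(1, 502, 200),
                         strut_records(1, 2, 200), 10, 504)
  expect_equal(m3$pairs$distance, 4)
})

test_that("optimal matching agrees with the exhaustive assignment oracle", {
  set.seed(71)
  for (i in 1:40) {
    nt <- sample(2:6, 1); nd <- sample(2:6, 1)
    truth <- strut_records(1, sample(1:64, nt), sample(1:80, nt))
    det <- strut_records(1, sample(1:64, nd), sample(1:80, nd))
    acc <- sample(c(5, 10, 20), 1)
    m <- match_detections(det, truth, acc, 64)
    cost <- outer(seq_len(nt), seq_len(nd), function(a, b)
      pixel_dist(truth$aline[a], truth$depth[a],
                 det$aline[b], det$depth[b], 64))
    want <- oracle_assignment(cost, acc)
    expect_equal(nrow(m$pairs), want$n_matches)
    if (want$n_matches > 0)
      expect_equal(sum(m$pairs$distance), want$total, tolerance = 1e-9)
  }
})

test_that("report fields follow the sensitivity and FP definitions", {
  set.seed(72)
  truth <- strut_records(rep(1:10, each = 10),
                         rep(seq(10, 120, length.out = 10), 10),
                         sample(40:80, 100, TRUE))
  # detect 94, add 4 false positives
  det <- truth[1:94, ]
  fp <- strut_records(1:4, rep(64, 4), rep(200, 4))
  rep <- evaluate_detections(rbind(det, fp), truth, 10, 128)
  expect_equal(rep$n_truth, 100)
  expect_equal(rep$n_true_positive, 94)
  expect_equal(rep$n_false_positive, 4)
  expect_equal(rep$sensitivity, 0.94)
  expect_equal(rep$fp_ratio, 0.04)
  expect_equal(rep$distance_mean_px, 0)

  # sensitivity + unmatched fraction = 1
  m <- attr(rep, "matching")
  expect_equal(rep$sensitivity + length(m$unmatched_truth) / rep$n_truth, 1)

  zero <- evaluate_detections(strut_records(), truth, 10, 128)
  expect_equal(zero$sensitivity, 0)
  expect_equal(zero$fp_ratio, 0)
})

test_that("per-status breakdown sums to the overall counts", {
  truth <- strut_records(rep(1, 6), seq(10, 110, by = 20), rep(50, 6))
  truth$status <- rep(c("apposed", "covered", "malapposed"), 2)
  det <- truth[c(1, 2, 3, 5), 1:4]
  rep <- evaluate_detections(det, truth, 10, 128)
  expect_equal(sum(rep$by_status$n_truth), 6)
  expect_equal(sum(rep$by_status$n_true_positive), rep$n_true_positive)
  expect_equal(rep$by_status$sensitivity[rep$by_status$status == "covered"], 1)
})

test_that("inter-observer agreement is symmetric", {
  set.seed(73)
  a <- strut_records(rep(1:5, each = 8), sample(1:128, 40, TRUE),
                     sample(1:200, 40, TRUE))
  b <- a[sample(40, 35), ]
  b$depth <- b$depth + sample(-3:3, 35, TRUE)
  ab <- interobserver_agreement(a, b, 10, 128)
  ba <- interobserver_agreement(b, a, 10, 128)
  expect_equal(ab$agreement, ba$agreement)
  expect_equal(ab$n_matches, ba$n_matches)
  expect_equal(ab$agreement, ab$n_matches / mean(c(nrow(a), nrow(b))))
})

test_that("evaluation reports serialize and round-trip", {
  truth <- strut_records(rep(1, 4), c(10, 40, 70, 100), rep(50, 4))
  rep <- evaluate_detections(truth, truth, 10, 128)
  path <- withr::local_tempfile(fileext = ".json")
  out <- unclass(rep)
  out$by_status <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$sensitivity, rep$sensitivity)
  expect_equal(back$n_truth, rep$n_truth)
  expect_equal(back$distance_mean_px, rep$distance_mean_px)
})

test_that("the parameter sweep reruns five parameters at three deltas", {
  ph <- suite_phantom("high_quality", n_frames = 6)
  p <- scaled_params()
  sw <- parameter_sweep(ph$pullback, ph$truth, p)
  expect_equal(nrow(sw), 15)
  expect_equal(length(unique(sw$parameter)), 5)
  base <- detect_struts(ph$pullback, p)
  ev <- evaluate_detections(base$struts, ph$truth, p$acceptance_distance, 128)
  zero <- sw[sw$delta == 0, ]
  expect_true(all(zero$sensitivity == ev$sensitivity))
  expect_true(all(zero$fp_ratio == ev$fp_ratio))
  expect_true(all(zero$distance_mean_px == ev$distance_mean_px))
})
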