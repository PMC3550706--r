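# Synthetic strut tables: struts at fixed A-lines/depth plus an optional
# wire-like chain near the catheter.
make_struts <- function(n_frames, wire_depth = NULL, wire_drift = 0.5,
                        miss_frames = integer(0)) {
  out <- list()
  for (f in seq_len(n_frames)) {
    s <- strut_records(frame = rep(f, 3), aline = c(40, 80, 120),
                       depth = c(60, 70, 65))
    if (!is.null(wire_depth) && !(f %in% miss_frames)) {
      w <- strut_records(f, round(10 + wire_drift * (f - 1)), wire_depth)
      s <- rbind(s, w)
    }
    out[[f]] <- s
  }
  do.call(rbind, out)
}

test_that("a continuous near-catheter chain is detected as the guide wire", {
  s <- make_struts(30, wire_depth = 20)
  tr <- detect_guide_wire(s, 30, 160, distance_threshold = 11,
                          min_track_fraction = 0.8)
  expect_equal(nrow(tr), 30)
  expect_equal(tr$depth, rep(20, 30))

  # a single missed frame does not sever the track
  s2 <- make_struts(30, wire_depth = 20, miss_frames = 15)
  tr2 <- detect_guide_wire(s2, 30, 160, 11, 0.8)
  expect_equal(nrow(tr2), 29)
  expect_false(15 %in% tr2$frame)
})

test_that("no track is reported without a continuous chain", {
  # struts only: the minimal-depth strut changes identity across frames
  set.seed(61)
  out <- list()
  for (f in 1:30) {
    d <- sample(c(60, 70, 65))
    out[[f]] <- strut_records(rep(f, 3), c(40, 80, 120), d)
  }
  s <- do.call(rbind, out)
  expect_null(detect_guide_wire(s, 30, 160, 11, 0.8))
  # single frame: continuity is undefined
  expect_null(detect_guide_wire(make_struts(1, wire_depth = 20), 1, 160, 11, 0.8))
  # short chain below the coverage fraction
  s3 <- make_struts(30, wire_depth = 20, miss_frames = seq(3, 30, by = 3))
  expect_null(detect_guide_wire(s3, 30, 160, 11, 0.8))
})

test_that("guide-wire removal flags at most one detection per frame", {
  s <- make_struts(20, wire_depth = 20)
  tr <- detect_guide_wire(s, 20, 160, 11, 0.8)
  out <- remove_guide_wire(s, tr, 160, acceptance_distance = 3)
  flagged <- out[out$kind == "guide_wire_removed", ]
  expect_equal(nrow(flagged), 20)
  expect_lte(max(table(flagged$frame)), 1)
  expect_true(all(flagged$depth == 20))
  # no track: identity
  expect_identical(remove_guide_wire(s, NULL, 160, 3), s)
  # struts far from the track are never flagged
  expect_equal(sum(out$kind == "bright"), 60)
})

test_that("the stented segment is the long run of strut-rich frames", {
  counts <- c(rep(0, 10), rep(8, 30), rep(0, 10))
  out <- list()
  for (f in seq_along(counts)) {
    if (counts[f] > 0)
      out[[length(out) + 1]] <-
        strut_records(rep(f, counts[f]), seq(8, by = 16, length.out = counts[f]),
                      rep(60, counts[f]))
  }
  s <- do.call(rbind, out)
  seg <- detect_stented_segment(s, 50, segment_min_count = 3,
                                segment_smooth_window = 5)
  expect_true(abs(seg$segment[1] - 11) <= 2)
  expect_true(abs(seg$segment[2] - 40) <= 2)
  act <- seg$struts[seg$struts$kind %in% c("bright", "non_bright"), ]
  expect_true(all(act$frame >= seg$segment[1] & act$frame <= seg$segment[2]))
  flagged <- seg$struts$kind == "outside_segment_removed"
  expect_true(all(seg$struts$frame[flagged] < seg$segment[1] |
                  seg$struts$frame[flagged] > seg$segment[2]))

  # uniform counts: the whole pullback is the segment
  s2 <- make_struts(20)
  seg2 <- detect_stented_segment(s2, 20, 3, 5)
  expect_equal(seg2$segment, c(1, 20))

  # no struts at all: empty segment, everything flagged
  seg3 <- detect_stented_segment(strut_records(), 20, 3, 5)
  expect_null(seg3$segment)
  s4 <- strut_records(c(3, 17), c(10, 20), c(30, 40))
  seg4 <- detect_stented_segment(s4, 20, 3, 5)
  expect_null(seg4$segment)
  expect_true(all(seg4$struts$kind == "outside_segment_removed"))
})
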