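test_that("a symmetric annulus partitions into six near-equal segments", {
  g <- phantom_geometry(grid_size = 256L, pixel_spacing = 0.5, n_slices = 1L,
                        endo_radius = 15, epi_radius = 25,
                        mi_angular_span = 0, imh_angular_span = 0)
  lm <- build_label_map(g)
  myo <- ground_truth(lm)$masks$lv_myo
  part <- partition_slice(myo, center = g$lv_center, n_segments = 6L)
  areas <- tabulate(part[part > 0], nbins = 6)
  expect_lt((max(areas) - min(areas)) / mean(areas), 0.02)
})

test_that("boundary pixels join the lower-indexed segment", {
  # 21x21 grid, center at (10,10): the pixel due 'north' lies exactly at
  # 90 degrees, the boundary between segments 1 and 2 for n_segments = 4
  myo <- matrix(TRUE, 21, 21)
  part <- partition_slice(myo, center = c(10, 10), ref_angle = 0,
                          n_segments = 4L)
  expect_equal(part[5, 11], 1L)   # theta = 90: boundary -> segment 1
  expect_equal(part[11, 16], 1L)  # theta = 0 belongs to segment 1
  expect_equal(part[5, 10], 2L)   # just past 90 degrees -> segment 2
})

test_that("rotating the reference by one sector width permutes segment ids", {
  g <- small_geometry(mi_angular_span = 0, imh_angular_span = 0)
  myo <- ground_truth(build_label_map(g))$masks$lv_myo
  p0 <- partition_slice(myo, center = g$lv_center, ref_angle = 0, n_segments = 6L)
  p1 <- partition_slice(myo, center = g$lv_center, ref_angle = 60, n_segments = 6L)
  a0 <- tabulate(p0[p0 > 0], 6)
  a1 <- tabulate(p1[p1 > 0], 6)
  expect_equal(sort(a0), sort(a1))
  # the rotation maps segment k+1 of the rotated frame onto k of the original
  inside <- p0 > 0
  expect_true(all((p0[inside] - p1[inside]) %% 6 == 1))
})

test_that("segment measurements report exact area fractions", {
  part <- matrix(0L, 25, 16)
  part[1:25, 1:16] <- 1L           # one segment of 400 px
  attr(part, "n_segments") <- 6L
  hypo <- matrix(FALSE, 25, 16)
  hypo[1, 1:5] <- TRUE             # 5 hypointense px
  m <- segment_measurements(hypo, part)
  expect_equal(nrow(m), 1)
  expect_equal(m$myo_area_px, 400)
  expect_equal(m$hypo_fraction, 0.0125)
  # trivial limits
  m0 <- segment_measurements(matrix(FALSE, 25, 16), part)
  expect_equal(m0$hypo_fraction, 0)
  m1 <- segment_measurements(part > 0, part)
  expect_equal(m1$hypo_fraction, 1)
})

test_that("the 1% positivity rule is strict and exclusions drop segments", {
  meas <- data.frame(slice = 1, segment = 1:4,
                     myo_area_px = c(400, 400, 400, 400),
                     hypo_area_px = c(5, 4, 0, 200),
                     hypo_fraction = c(0.0125, 0.01, 0, 0.5))
  calls <- call_segments(meas)
  expect_equal(calls$positive, c(TRUE, FALSE, FALSE, TRUE))
  calls_x <- call_segments(meas, exclude = 4L)
  ct <- contingency(calls_x, calls_x)
  expect_equal(ct$n, 3)           # excluded segment absent from the table
  expect_equal(ct$tp, 1)
  expect_error(call_segments(meas, positivity_threshold = 0), "0, 1")
})

test_that("contingency cross-tabulates and rejects mismatched sets", {
  mk <- function(pos) data.frame(slice = 1, segment = seq_along(pos),
                                 myo_area_px = 100, hypo_area_px = 0,
                                 hypo_fraction = 0, positive = pos,
                                 excluded = FALSE)
  ct <- contingency(mk(c(TRUE, TRUE, FALSE, FALSE, FALSE)),
                    mk(c(TRUE, FALSE, TRUE, FALSE, FALSE)))
  expect_equal(unclass(ct)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 1L, fn = 1L, tn = 2L))
  ident <- contingency(mk(rep(c(TRUE, FALSE), c(10, 20))),
                       mk(rep(c(TRUE, FALSE), c(10, 20))))
  expect_equal(ident$tp, 10); expect_equal(ident$tn, 20)
  expect_equal(ident$fp + ident$fn, 0)
  allneg <- contingency(mk(rep(FALSE, 30)), mk(rep(c(TRUE, FALSE), c(10, 20))))
  expect_equal(allneg$fn, 10)
  expect_error(contingency(mk(c(TRUE, FALSE)), mk(c(TRUE, FALSE, TRUE))),
               "different segment sets")
})

test_that("dx_summary computes the paper's accuracy definition and NA contracts", {
  ct <- structure(list(tp = 9L, fp = 2L, tn = 18L, fn = 1L, n = 30L),
                  class = "contingency")
  s <- dx_summary(ct)
  expect_equal(s$sensitivity, 0.9)
  expect_equal(s$specificity, 0.9)
  expect_equal(s$accuracy, 27 / 30)
  # no reference positives => sensitivity undefined, never silently 0
  ct0 <- structure(list(tp = 0L, fp = 2L, tn = 18L, fn = 0L, n = 20L),
                   class = "contingency")
  s0 <- dx_summary(ct0, test_fractions = runif(20), ref_calls = rep(FALSE, 20))
  expect_true(is.na(s0$sensitivity))
  expect_true(is.na(s0$auc))
})

test_that("accuracy decomposes as sens*prev + spec*(1-prev)", {
  set.seed(99)
  for (i in 1:25) {
    tp <- sample(0:20, 1); fn <- sample(0:20, 1)
    fp <- sample(0:20, 1); tn <- sample(0:20, 1)
    if (tp + fn == 0 || tn + fp == 0) next
    ct <- structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                         n = tp + fp + tn + fn), class = "contingency")
    s <- dx_summary(ct)
    prev <- (tp + fn) / ct$n
    expect_equal(s$accuracy, s$sensitivity * prev + s$specificity * (1 - prev))
  }
})

test_that("rank-sum AUC handles separation and total ties", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_rank(rep(0.3, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_true(is.na(auc_rank(1:5, rep(TRUE, 5))))
})

test_that("rank-sum AUC equals the exhaustive ROC-sweep oracle", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    # mix continuous scores with heavy ties
    scores <- if (i %% 2 == 0) rnorm(n) else sample(0:3, n, replace = TRUE) / 3
    expect_equal(auc_rank(scores, labels), auc_sweep_oracle(scores, labels),
                 tolerance = 1e-10)
  }
})
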