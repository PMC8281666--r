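test_that("region_stats uses the population SD and enforces its contract", {
  img <- as_stack(matrix(c(4, 6, 1, 1), 2, 2))
  mask <- as_stack(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  st <- region_stats(img, mask)
  expect_equal(st$mean_si, 5)
  expect_equal(st$sd_si, 1)       # population SD of {4, 6}
  expect_equal(st$n_pixels, 2)
  const <- region_stats(array(7, c(3, 3, 1)), array(TRUE, c(3, 3, 1)))
  expect_equal(const$mean_si, 7)
  expect_equal(const$sd_si, 0)
  expect_error(region_stats(img, array(TRUE, c(3, 3, 1))), "dimensions")
  expect_error(region_stats(img, array(FALSE, c(2, 2, 1))), "no pixels")
})

test_that("remote ROI sits opposite the infarct and never touches it", {
  subj <- simulate_subject(small_config(), seed = 4)
  myo <- subj$truth$masks$lv_myo
  mi <- subj$truth$masks$mi_zone
  for (seed in 1:100) {
    roi <- select_remote_roi(subj$lge, myo, mi, jitter_seed = seed)
    expect_false(any(roi & mi))
    expect_true(all(myo[roi]))
  }
  r1 <- select_remote_roi(subj$lge, myo, mi, jitter_seed = 42)
  r2 <- select_remote_roi(subj$lge, myo, mi, jitter_seed = 42)
  expect_identical(r1, r2)
})

test_that("without an infarct the ROI faces the reference angle + 180", {
  lm <- build_label_map(small_geometry(mi_angular_span = 0, imh_angular_span = 0,
                                       stagnant_layer_thickness = 0))
  tr <- ground_truth(lm)
  roi <- select_remote_roi(array(0, dim(lm$labels)), tr$masks$lv_myo,
                           array(FALSE, dim(lm$labels)))
  expect_equal(attr(roi, "center_angle"), 180)
})

test_that("the 5-SD infarct rule applies the threshold inclusively", {
  # remote pixels {46, 54}: mean 50, population SD 4 => threshold 70
  img <- matrix(0, 4, 4)
  img[1, 1] <- 46; img[1, 2] <- 54
  img[2, 1] <- 60; img[2, 2] <- 70; img[2, 3] <- 95
  roi <- matrix(FALSE, 4, 4); roi[1, 1:2] <- TRUE
  myo <- matrix(FALSE, 4, 4); myo[2, 1:3] <- TRUE
  det <- detect_mi_zone(as_stack(img), as_stack(myo), as_stack(roi))
  expect_equal(det$threshold, 70)
  expect_equal(as.vector(det$mask[2, 1:3, 1]), c(FALSE, TRUE, TRUE))
  expect_false(det$degenerate)
})

test_that("the 2-SD hemorrhage rule flags pixels at or below the threshold", {
  # remote {95, 105}: mean 100, SD 5 => threshold 90
  img <- matrix(100, 4, 4)
  img[1, 1] <- 95; img[1, 2] <- 105
  img[3, 1] <- 95; img[3, 2] <- 88; img[3, 3] <- 70; img[3, 4] <- 92
  roi <- matrix(FALSE, 4, 4); roi[1, 1:2] <- TRUE
  mi <- matrix(FALSE, 4, 4); mi[3, ] <- TRUE
  det <- detect_imh(as_stack(img), as_stack(mi), as_stack(roi),
                    min_core_pixels = 1)
  expect_equal(det$threshold, 90)
  expect_equal(as.vector(det$mask[3, , 1]), c(FALSE, TRUE, TRUE, FALSE))
})

test_that("small cores below min_core_pixels are discarded (4-connectivity)", {
  img <- matrix(100, 8, 8)
  roi <- matrix(FALSE, 8, 8); roi[1, 1:2] <- TRUE
  img[1, 1] <- 95; img[1, 2] <- 105
  mi <- matrix(TRUE, 8, 8)
  img[4, 4] <- 50                      # isolated single pixel
  img[6, 6] <- 50; img[7, 6] <- 50     # 4-connected pair
  img[2, 7] <- 50; img[3, 8] <- 50     # diagonal neighbors: NOT 4-connected
  det <- detect_imh(as_stack(img), as_stack(mi), as_stack(roi),
                    min_core_pixels = 2)
  expect_false(det$mask[4, 4, 1])
  expect_true(det$mask[6, 6, 1] && det$mask[7, 6, 1])
  expect_false(det$mask[2, 7, 1] || det$mask[3, 8, 1])
})

test_that("hemorrhage detection is invariant to joint affine rescaling", {
  subj <- simulate_subject(small_config(), seed = 8)
  roi <- select_remote_roi(subj$lge, subj$truth$masks$lv_myo,
                           subj$truth$masks$mi_zone)
  mi <- subj$truth$masks$mi_zone
  det1 <- detect_imh(subj$bright, mi, roi)
  scaled <- 3.7 * subj$bright$intensity + 11
  det2 <- detect_imh(scaled, mi, roi)
  expect_identical(det1$mask, det2$mask)
})

test_that("noise-free simulation recovers the truth masks and extent exactly", {
  for (field in c("1.5T", "3T")) for (phase in c("acute", "chronic")) {
    subj <- simulate_subject(subject_config(field, phase, grid_size = 96,
                                            n_slices = 2, noise_sigma = 0,
                                            lge = lge_contrast(noise_sigma = 0)),
                             seed = 13)
    for (arm in c("bright", "dark")) {
      seg <- quantify_subject(subj, arm)
      expect_identical(seg$mi_mask, subj$truth$masks$mi_zone)
      expect_identical(seg$imh_mask & TRUE, subj$truth$masks$IMH)
      expect_equal(seg$imh_extent_pct, subj$truth$true_imh_extent)
    }
  }
})

test_that("no-contrast images yield empty detections", {
  lm <- build_label_map(small_geometry())
  tr <- ground_truth(lm)
  flat_lge <- render_lge(lm, suppressWarnings(
    lge_contrast(mu_remote = 50, mu_mi = 50, noise_sigma = 0)))
  roi <- select_remote_roi(flat_lge, tr$masks$lv_myo, tr$masks$mi_zone)
  det <- suppressWarnings(detect_mi_zone(flat_lge, tr$masks$lv_myo, roi))
  expect_equal(sum(det$mask), 0)
  expect_true(det$degenerate)
  # IMH signal equal to remote => empty IMH mask
  flat <- array(1, dim(lm$labels))
  det2 <- detect_imh(flat, tr$masks$mi_zone, roi, min_core_pixels = 1)
  expect_equal(sum(det2$mask), 0)
})

test_that("imh_extent follows its definition", {
  myo <- array(FALSE, c(40, 40, 1)); myo[1:25, 1:40, 1] <- TRUE  # 1000 voxels
  imh <- array(FALSE, c(40, 40, 1)); imh[1:5, 1:10, 1] <- TRUE   # 50 voxels
  expect_equal(imh_extent(imh, myo), 5)
  expect_equal(imh_extent(array(FALSE, c(40, 40, 1)), myo), 0)
  expect_equal(imh_extent(myo, myo), 100)
  expect_error(imh_extent(imh, array(FALSE, c(40, 40, 1))), "empty")
  expect_error(imh_extent(imh[1:10, , , drop = FALSE], myo), "slice-matched")
})

test_that("expected measured extent shrinks as noise grows", {
  geom <- phantom_geometry(grid_size = 96L, pixel_spacing = 2, n_slices = 1L)
  sigmas <- c(0.005, 0.018, 0.030)
  means <- vapply(sigmas, function(sg) {
    ext <- vapply(1:50, function(s) {
      subj <- simulate_subject(subject_config("1.5T", "acute", geometry = geom,
                                              noise_sigma = sg), seed = s)
      quantify_subject(subj, "bright")$imh_extent_pct
    }, numeric(1))
    mean(ext)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})
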