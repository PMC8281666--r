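test_that("bright-blood signal reaches its closed-form limits", {
  tis <- list(T1 = 950, T2star = 30, PD = 0.8)
  # TE = 0 and RR >> T1: no T2* decay, full recovery => S = PD sin(alpha)
  sq <- sequence_params("bright", "1.5T", TE = 0, RR = 1e9, flip_angle = 18,
                        noise_sigma = 0)
  expect_equal(steady_state_signal(tis, sq), 0.8 * sin(18 * pi / 180),
               tolerance = 1e-12)
  expect_error(steady_state_signal(list(T1 = -1, T2star = 30, PD = 1), sq),
               "positive")
})

test_that("a perfect DIR pair with full recovery is the identity", {
  tis <- tissue_presets("1.5T", "acute")$REMOTE_MYO
  sqb <- sequence_params("bright", "1.5T", noise_sigma = 0)
  sqd <- sequence_params("dark", "1.5T", RR = 1e6, TI = 999999,
                         eta_nonsel = 1, eta_sel = 1, kappa = 1,
                         noise_sigma = 0)
  sqb_long <- sequence_params("bright", "1.5T", RR = 1e6, noise_sigma = 0)
  expect_equal(steady_state_signal(tis, sqd), steady_state_signal(tis, sqb_long),
               tolerance = 1e-9)
  # and with default TI/efficiencies, dark never exceeds bright
  expect_lt(steady_state_signal(tis, sequence_params("dark", "1.5T")),
            steady_state_signal(tis, sqb))
})

test_that("flowing blood is nulled at TI = T1 ln 2 for an ideal inversion", {
  null_ti <- 1400 * log(2)  # 970.4 ms
  f <- dir_recovery_fraction(1400, null_ti, eta_nonsel = 1, eta_sel = 1,
                             kappa = 1, flowing = TRUE)
  expect_equal(f, 0, tolerance = 1e-12)
  # signed fraction crosses zero: negative before the null, positive after
  expect_lt(dir_recovery_fraction(1400, null_ti - 50, 1, 1, 1, TRUE), 0)
  expect_gt(dir_recovery_fraction(1400, null_ti + 50, 1, 1, 1, TRUE), 0)
  # magnitude signal is zero at the null
  tis <- list(T1 = 1400, T2star = 40, PD = 0.95, flowing = TRUE)
  sq <- sequence_params("dark", "1.5T", TI = null_ti, RR = 1e5,
                        eta_nonsel = 1, eta_sel = 1, kappa = 1, noise_sigma = 0)
  expect_equal(steady_state_signal(tis, sq), 0, tolerance = 1e-12)
})

test_that("dark/bright remote ratio is bounded by 1 and monotone in eta and kappa", {
  etas <- seq(0.5, 0.99, by = 0.07)
  kappas <- seq(0.05, 1, by = 0.12)
  tis <- seq(300, 800, by = 100)
  for (ti in tis) {
    grid <- outer(etas, kappas, function(e, k) {
      dark_bright_ratio(T1 = 950, TI = ti, eta_nonsel = e, kappa = k)
    })
    expect_true(all(grid <= 1))
    # non-decreasing along eta (rows) and kappa (columns)
    expect_true(all(apply(grid, 2, function(col) all(diff(col) >= 0))))
    expect_true(all(apply(grid, 1, function(row) all(diff(row) >= 0))))
  }
  # equality holds only for a perfect preparation; any imperfection at
  # finite TI keeps the ratio strictly below 1
  expect_equal(dark_bright_ratio(950, 1e9, eta_nonsel = 1, kappa = 1), 1)
  expect_equal(dark_bright_ratio(950, 600, eta_nonsel = 1, kappa = 1), 1)
  expect_lt(dark_bright_ratio(950, 600, eta_nonsel = 0.99, kappa = 1), 1)
  expect_lt(dark_bright_ratio(950, 600, eta_nonsel = 1, kappa = 0.99), 1)
})

test_that("3T preset loses more dark-blood signal than 1.5T", {
  r15 <- with(sequence_params("dark", "1.5T"),
              dark_bright_ratio(950, TI, eta_nonsel, eta_sel, kappa))
  r3 <- with(sequence_params("dark", "3T"),
             dark_bright_ratio(1200, TI, eta_nonsel, eta_sel, kappa))
  expect_lt(r3, r15)
  expect_lt(r15, 1)
})

test_that("noise-free renders reproduce the signal table exactly", {
  lm <- build_label_map(small_geometry())
  tis <- tissue_presets("1.5T", "acute")
  sq <- sequence_params("bright", "1.5T", noise_sigma = 0)
  img <- render_image(lm, tis, sq)
  tab <- signal_table(tis, sq)
  for (cls in names(TISSUE_CLASSES)) {
    mask <- lm$labels == TISSUE_CLASSES[[cls]]
    if (any(mask)) expect_true(all(img$intensity[mask] == tab[[cls]]))
  }
})

test_that("rendering is deterministic under seed and Rician in the air background", {
  lm <- build_label_map(small_geometry())
  tis <- tissue_presets("1.5T", "acute")
  sq <- sequence_params("bright", "1.5T")
  a <- render_image(lm, tis, sq, seed = 5)
  b <- render_image(lm, tis, sq, seed = 5)
  c <- render_image(lm, tis, sq, seed = 6)
  expect_identical(a$intensity, b$intensity)
  expect_false(identical(a$intensity, c$intensity))
  expect_true(all(a$intensity >= 0))
  # air background is Rayleigh: mean sigma*sqrt(pi/2) (checked on a large
  # fine-grid air region)
  big <- build_label_map(phantom_geometry(grid_size = 192L, n_slices = 4L,
                                          epi_radius = 25))
  img <- render_image(big, tis, sq, seed = 1)
  air <- big$labels == TISSUE_CLASSES[["AIR"]]
  expect_lt(abs(mean(img$intensity[air]) / (sq$noise_sigma * sqrt(pi / 2)) - 1),
            0.02)
})

test_that("stagnant blood follows the in-slice formula in the dark arm", {
  cfg <- small_config(noise_sigma = 0)
  subj <- simulate_subject(cfg, seed = 3)
  stag <- subj$truth$masks$BLOOD_STAGNANT
  flow <- subj$truth$masks$BLOOD_FLOWING
  expect_gt(sum(stag), 0)
  tis <- tissue_presets("1.5T", "acute")
  sqd <- subj$dark$meta$seq
  stag_tissue <- tis$BLOOD_STAGNANT
  flow_as_static <- utils::modifyList(tis$BLOOD_FLOWING, list(flowing = FALSE))
  expect_equal(unique(subj$dark$intensity[stag]),
               steady_state_signal(stag_tissue, sqd))
  # flowing blood is suppressed well below the stagnant layer
  expect_lt(unique(subj$dark$intensity[flow]),
            unique(subj$dark$intensity[stag]))
  # and the stagnant value equals what flowing blood would give if static
  expect_equal(unique(subj$dark$intensity[stag]),
               steady_state_signal(flow_as_static, sqd))
})

test_that("chronic phase shrinks the true hemorrhage at a fixed seed", {
  for (seed in c(2, 9, 17)) {
    ac <- simulate_subject(subject_config("1.5T", "acute", grid_size = 96,
                                          n_slices = 1), seed)
    ch <- simulate_subject(subject_config("1.5T", "chronic", grid_size = 96,
                                          n_slices = 1), seed)
    expect_lt(sum(ch$truth$masks$IMH), sum(ac$truth$masks$IMH))
  }
})

test_that("a fixed subject seed reproduces the truth and images bit-identically", {
  s1 <- simulate_subject(small_config(), seed = 21)
  s2 <- simulate_subject(small_config(), seed = 21)
  expect_identical(s1$truth$true_imh_extent, s2$truth$true_imh_extent)
  expect_identical(s1$bright$intensity, s2$bright$intensity)
  expect_identical(s1$dark$intensity, s2$dark$intensity)
  expect_identical(s1$lge$intensity, s2$lge$intensity)
})

test_that("LGE warns when the MI mean sits too close to remote", {
  lm <- build_label_map(small_geometry())
  expect_warning(render_lge(lm, lge_contrast(mu_remote = 50, mu_mi = 60,
                                             noise_sigma = 4), seed = 1),
                 "unstable")
  expect_silent(render_lge(lm, lge_contrast(), seed = 1))
})
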