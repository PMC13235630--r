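test_that("quality metrics have their closed-form values and SSIM matches the reference implementation", {
  atl <- toy_atlas()
  mask <- atl$labels != 0L
  v <- random_toy_volume()
  q0 <- quality_metrics(v, v, mask)
  expect_identical(q0$mse, 0)
  expect_identical(q0$psnr, Inf)
  expect_equal(q0$ssim, 1, tolerance = 1e-12)

  shifted <- toy_volume(v$data + 0.3)
  q1 <- quality_metrics(v, shifted, mask)
  expect_equal(q1$mse, 0.3^2, tolerance = 1e-12)
  expect_equal(q1$psnr, 10 * log10(max(v$data[mask])^2 / 0.3^2),
               tolerance = 1e-12)

  # frozen scikit-image oracle on a deterministic 40x40 fixture
  fx <- ssim_fixture()
  a <- pet_volume(array(fx$x, dim = c(40, 40, 1)))
  b <- pet_volume(array(fx$y, dim = c(40, 40, 1)))
  full <- array(TRUE, dim = c(40, 40, 1))
  q <- quality_metrics(a, b, full)
  expect_equal(q$ssim, fx$expected, tolerance = 1e-6)

  expect_error(quality_metrics(a, v, full), "shapes differ")
  expect_error(quality_metrics(a, b, array(FALSE, c(40, 40, 1))), "empty")
})

test_that("ROI means match the brute-force label scan and the fixed order", {
  atl <- toy_atlas()
  # each GM region holds exactly 4 voxels: plant 1,2,3,4 in one of them
  dat <- array(0.5, dim = c(12, 12, 4))
  dat[atl$labels == 3L] <- c(1, 2, 3, 4)
  v <- toy_volume(dat)
  tab <- roi_means(v, atl)
  expect_identical(nrow(tab), 10L)
  expect_identical(tab$region, roi_feature_order())
  expect_equal(tab$mean[tab$region == "temporal_L"], 2.5)

  const <- toy_volume(array(1.7, dim = c(12, 12, 4)))
  expect_true(all(roi_means(const, atl)$mean == 1.7))

  set.seed(31)
  v2 <- random_toy_volume()
  tab2 <- roi_means(v2, atl)
  for (i in 1:10) {
    gid <- atl$regions$region_id[match(paste0(tab2$region[i], "_GM"),
                                       atl$regions$name)]
    expect_equal(tab2$mean[i], bf_region_mean(v2, atl, gid), tolerance = 1e-12)
  }
})

test_that("white/gray contrast reproduces the formula, antisymmetry and oracle", {
  atl <- toy_atlas()
  # muW = 2, muG = 1, sigmaW = sigmaG = 0.5 -> contrast = 1
  dat <- array(0, dim = c(12, 12, 4))
  dat[atl$labels == 1L] <- c(0.5, 1.5, 0.5, 1.5)   # GM frontal_insular L
  dat[atl$labels == 11L] <- c(1.5, 2.5, 1.5, 2.5)  # paired WM
  v <- toy_volume(dat)
  rec <- wg_contrast(v, atl, "frontal_insular", "L")
  expect_equal(rec$mu_w, 2)
  expect_equal(rec$mu_g, 1)
  expect_equal(rec$sigma_w, 0.5)
  expect_equal(rec$sigma_g, 0.5)
  expect_equal(rec$contrast, 1)

  # swapping the two regions' voxels negates the contrast
  dat2 <- dat
  dat2[atl$labels == 1L] <- c(1.5, 2.5, 1.5, 2.5)
  dat2[atl$labels == 11L] <- c(0.5, 1.5, 0.5, 1.5)
  expect_equal(wg_contrast(toy_volume(dat2), atl, "frontal_insular", "L")$contrast,
               -1)

  set.seed(41)
  for (rep in 1:10) {
    v3 <- random_toy_volume()
    rec3 <- wg_contrast(v3, atl, "parietal", "R")
    expect_equal(rec3$contrast, bf_contrast(v3, atl, 6L, 16L),
                 tolerance = 1e-12)
  }

  # degenerate: both regions constant -> error, not infinity
  expect_error(wg_contrast(toy_volume(array(1, dim = c(12, 12, 4))), atl,
                           "striatum", "L"), "degenerate")
})

test_that("contrast is invariant under global scaling and shifts", {
  atl <- toy_atlas()
  set.seed(51)
  for (rep in 1:10) {
    v <- random_toy_volume()
    base <- wg_contrast(v, atl, "temporal", "L")$contrast
    a <- runif(1, 0.2, 5)
    b <- runif(1, -2, 2)
    scaled <- toy_volume(v$data * a)
    shifted <- toy_volume(v$data + b)
    expect_equal(wg_contrast(scaled, atl, "temporal", "L")$contrast, base,
                 tolerance = 1e-10)
    expect_equal(wg_contrast(shifted, atl, "temporal", "L")$contrast, base,
                 tolerance = 1e-10)
  }
})

test_that("linear_fit matches closed forms and the normal-equation oracle", {
  x <- c(1, 2, 3, 4, 5)
  fit <- linear_fit(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # textbook 5-point set against the normal equations
  xt <- c(1.2, 2.8, 3.1, 4.7, 5.5)
  yt <- c(2.3, 3.1, 4.8, 5.2, 7.0)
  ft <- linear_fit(xt, yt)
  bf <- bf_ols(xt, yt)
  expect_equal(ft$slope, unname(bf["slope"]), tolerance = 1e-12)
  expect_equal(ft$intercept, unname(bf["intercept"]), tolerance = 1e-12)
  expect_true(ft$slope_lo <= ft$slope & ft$slope <= ft$slope_hi)

  # regression of a variable on itself
  set.seed(61)
  z <- rnorm(50)
  fid <- linear_fit(z, z)
  expect_equal(fid$slope, 1, tolerance = 1e-12)
  expect_equal(fid$r_squared, 1, tolerance = 1e-12)

  # y independent of x: slope near zero, p not extreme
  set.seed(62)
  ps <- replicate(20, {
    x <- rnorm(100)
    y <- sample(rnorm(100))
    f <- linear_fit(x, y)
    expect_lt(abs(f$slope), 0.5)
    f$p_slope
  })
  expect_gt(mean(ps > 0.05), 0.5)  # most null fits are non-significant
  expect_error(linear_fit(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(linear_fit(1:3, 1:4), "mismatch")
})

test_that("one-sided Wilcoxon matches exact enumeration and its conventions", {
  expect_equal(wilcoxon_onesided(c(3, 4), c(1, 2)), 1 / 6, tolerance = 1e-12)
  # identical samples: continuity-corrected p near one half
  a <- c(1, 2, 3, 4, 5)
  expect_equal(wilcoxon_onesided(a, a), 0.5, tolerance = 0.1)
  # exact path against brute-force enumeration
  set.seed(71)
  for (rep in 1:20) {
    a <- round(rnorm(sample(3:6, 1)), 6)
    b <- round(rnorm(sample(3:6, 1)) + 0.3, 6)
    expect_equal(wilcoxon_onesided(a, b), bf_wilcoxon_exact(a, b),
                 tolerance = 1e-10)
  }
  # exact and large-sample paths agree to ~0.02 at n = m = 6
  set.seed(72)
  for (rep in 1:10) {
    a <- rnorm(6)
    b <- rnorm(6)
    exact <- wilcoxon_onesided(a, b)
    approx <- suppressWarnings(
      wilcox.test(a, b, alternative = "greater", exact = FALSE,
                  correct = TRUE)$p.value
    )
    expect_lt(abs(exact - approx), 0.02)
  }
  expect_error(wilcoxon_onesided(numeric(0), 1), "empty")
})

test_that("fold evaluation recovers identity and affine relations exactly", {
  co <- small_cohort()
  atl <- small_atlas()
  studies <- co$studies
  ids <- cohort_ids(co)

  synth_id <- setNames(lapply(studies, function(s) s$amyloid), ids)
  ev <- evaluate_fold(studies, synth_id, atl)
  expect_equal(ev$voxel_fit$slope, 1, tolerance = 1e-12)
  expect_equal(ev$voxel_fit$intercept, 0, tolerance = 1e-12)
  expect_equal(ev$voxel_fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(ev$contrast_fit$slope, 1, tolerance = 1e-12)
  expect_true(all(ev$quality$mse == 0))
  expect_true(all(ev$quality$ssim > 1 - 1e-9))

  synth_aff <- setNames(lapply(studies, function(s) {
    pet_volume(0.5 * s$amyloid$data + 0.25, spacing = s$amyloid$spacing)
  }), ids)
  ev2 <- evaluate_fold(studies, synth_aff, atl)
  expect_equal(ev2$voxel_fit$slope, 0.5, tolerance = 1e-9)
  expect_equal(ev2$voxel_fit$intercept, 0.25, tolerance = 1e-9)

  expect_error(evaluate_fold(studies, synth_id[-1], atl), "do not match")
})
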