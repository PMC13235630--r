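test_that("reference normalization has unit region mean, idempotence and scale equivariance", {
  atl <- toy_atlas()
  const <- toy_volume(array(2, dim = c(12, 12, 4)))
  norm <- normalize_by_reference(const, atl, "reference")
  expect_true(all(norm$data == 1))
  set.seed(21)
  for (rep in 1:10) {
    v <- random_toy_volume()
    nv <- normalize_by_reference(v, atl, "reference")
    expect_equal(mean(nv$data[atl$labels == 21L]), 1, tolerance = 1e-9)
    # idempotent
    nv2 <- normalize_by_reference(nv, atl, "reference")
    expect_equal(nv2$data, nv$data, tolerance = 1e-12)
    # scale equivariant
    sv <- toy_volume(v$data * runif(1, 0.1, 10))
    expect_equal(normalize_by_reference(sv, atl, "reference")$data, nv$data,
                 tolerance = 1e-12)
    # wholebrain pseudo-region
    nw <- normalize_by_reference(v, atl, "wholebrain")
    expect_equal(mean(nw$data[atl$labels != 0L]), 1, tolerance = 1e-9)
  }
  zero <- toy_volume(array(0, dim = c(12, 12, 4)))
  expect_error(normalize_by_reference(zero, atl, "reference"), "nonpositive")
  expect_error(normalize_by_reference(const, atl, "no_such_region"), "unknown")
})

test_that("grid conformance is exact for identity and constants, linear for ramps", {
  v <- pet_volume(array(runif(16^3), dim = c(16, 16, 16)), spacing = c(2, 2, 2))
  same <- conform_grid(v, c(16, 16, 16))
  expect_identical(same$data, v$data)

  cv <- pet_volume(array(3.5, dim = c(10, 12, 8)))
  up <- conform_grid(cv, c(20, 24, 16))
  expect_equal(unname(as.numeric(up$data)), rep(3.5, 20 * 24 * 16),
               tolerance = 1e-12)
  expect_equal(up$spacing, cv$spacing / 2)

  # linear ramp along x, upsampled 2x: closed-form interpolation with
  # edge-clamped endpoints
  ramp <- array(rep(0:63, 64 * 30), dim = c(64, 64, 30))
  rv <- pet_volume(ramp, spacing = c(3, 3, 3))
  big <- conform_grid(rv, c(128, 128, 60))
  expect_identical(dim(big$data), c(128L, 128L, 60L))
  src <- pmin(pmax((0:127 + 0.5) * 0.5 - 0.5, 0), 63)
  expected <- pmin(src, 63)  # ramp value equals clamped source coordinate
  expect_equal(big$data[, 1, 1], expected, tolerance = 1e-9)
  expect_equal(big$data[1, 1, 1], 0)
  expect_equal(big$data[128, 1, 1], 63)
  expect_error(conform_grid(rv, c(1, 10, 10)), ">= 2")
})

test_that("slice extraction follows the brain mask and threshold", {
  atl <- small_atlas()
  study <- small_cohort()$studies[[1]]
  sl <- extract_slices(study, atl, brain_fraction_min = 0)
  expect_length(sl, dim(atl$labels)[3])
  sl2 <- extract_slices(study, atl, brain_fraction_min = 0.01)
  n_brain <- sum(apply(atl$labels != 0L, 3, mean) >= 0.01)
  expect_length(sl2, n_brain)
  expect_true(all(diff(vapply(sl2, `[[`, integer(1), "z_index")) > 0))
  expect_identical(sl2[[1]]$status, study$status)
  expect_identical(dim(sl2[[1]]$fdg_slice), dim(sl2[[1]]$amyloid_slice))
  expect_error(extract_slices(study, atl, brain_fraction_min = 1.01),
               "no slice")
  # FDG-only extraction for inference
  sl3 <- extract_slices(study$fdg, atl, brain_fraction_min = 0.01)
  expect_null(sl3[[1]]$amyloid_slice)
})

test_that("the canonical grid yields about 50 brain slices and >3000 training samples for 80 cases", {
  atl <- canonical_atlas()
  frac <- apply(atl$labels != 0L, 3, mean)
  n_slices <- sum(frac >= 0.01)
  expect_gte(n_slices, 45)
  expect_lte(n_slices, 55)
  expect_gt(80 * n_slices, 3000)
})

test_that("GAN range scaling is an exact affine inverse pair with clipping", {
  expect_equal(to_gan_range(c(0, 5, 10), 0, 10), c(-1, 0, 1))
  expect_equal(to_gan_range(11, 0, 10), 1)   # clipped above
  expect_equal(to_gan_range(-2, 0, 10), -1)  # clipped below
  set.seed(4)
  x <- runif(200, 0, 10)
  expect_equal(from_gan_range(to_gan_range(x, 0, 10), 0, 10), x,
               tolerance = 1e-12)
  expect_error(to_gan_range(1, 2, 2), "exceed")
  expect_error(from_gan_range(1, 3, 2), "exceed")
})

test_that("slice extraction and restacking reproduce the retained sub-volume", {
  atl <- small_atlas()
  study <- small_cohort()$studies[[2]]
  sl <- extract_slices(study, atl, brain_fraction_min = 0.01)
  rebuilt <- array(0, dim = dim(study$fdg$data))
  for (s in sl) rebuilt[, , s$z_index] <- s$fdg_slice
  keep <- vapply(sl, `[[`, integer(1), "z_index")
  expect_identical(rebuilt[, , keep], study$fdg$data[, , keep])
})
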