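test_that("generator and discriminator obey their shape contracts", {
  cfg <- gan_config_small(seed = 3)
  gen <- build_generator(cfg)
  x <- matrix(runif(64 * 64, -1, 1), 64, 64)
  y <- generator_forward(gen, x)
  expect_identical(dim(y), c(64L, 64L))
  expect_true(all(is.finite(y)))
  expect_true(all(y >= -1 & y <= 1))  # tanh output

  # constant input through the untrained net stays finite and in range
  yc <- generator_forward(gen, matrix(0.2, 64, 64))
  expect_true(all(is.finite(yc)) && all(abs(yc) <= 1))

  disc <- build_discriminator(cfg)
  dd <- discriminator_forward(disc, x, y)
  expect_identical(c(dd$hp, dd$wp), c(6L, 6L))
  expect_true(all(is.finite(dd$scores)))

  # the 70x70 PatchGAN arithmetic: 128 -> 14x14, 256 -> 30x30
  cfg128 <- gan_config(image_size = 128L, base_channels = 8L, seed = 1)
  d128 <- build_discriminator(cfg128)
  x128 <- matrix(runif(128 * 128), ncol = 1)
  p128 <- discriminator_forward(d128, matrix(x128, 128, 128),
                                matrix(x128, 128, 128))
  expect_identical(c(p128$hp, p128$wp), c(14L, 14L))
  x256 <- matrix(runif(256 * 256), 256, 256)
  p256 <- discriminator_forward(d128, x256, x256)
  expect_identical(c(p256$hp, p256$wp), c(30L, 30L))

  # 128x128 generator at full base width keeps the shape contract
  cfg_full <- gan_config(seed = 2)
  gfull <- build_generator(cfg_full)
  yfull <- generator_forward(gfull, matrix(runif(128 * 128, -1, 1), 128, 128))
  expect_identical(dim(yfull), c(128L, 128L))
  expect_true(all(abs(yfull) <= 1))

  expect_error(gan_config(image_size = 96L), "power of 2")
})

test_that("balanced minibatches hold exactly half of each class", {
  s <- fake_samples(100, 100)
  b <- make_balanced_minibatches(s, 20, seed = 1)
  expect_length(b, 10L)
  status <- vapply(s, `[[`, character(1), "status")
  for (batch in b) {
    expect_length(batch, 20L)
    expect_identical(sum(status[batch] == "positive"), 10L)
    expect_identical(sum(status[batch] == "negative"), 10L)
  }
  # all positives and negatives are used exactly once when counts match
  expect_setequal(unlist(b), seq_along(s))

  # minority oversampling: majority exhausted, every batch still balanced
  s2 <- fake_samples(60, 100)
  b2 <- make_balanced_minibatches(s2, 20, seed = 2)
  expect_length(b2, 10L)
  status2 <- vapply(s2, `[[`, character(1), "status")
  for (batch in b2) {
    expect_identical(sum(status2[batch] == "positive"), 10L)
    expect_identical(sum(status2[batch] == "negative"), 10L)
  }
  neg_used <- unlist(lapply(b2, function(x) x[status2[x] == "negative"]))
  expect_setequal(neg_used, which(status2 == "negative"))

  expect_identical(make_balanced_minibatches(s, 20, seed = 7),
                   make_balanced_minibatches(s, 20, seed = 7))
  expect_error(make_balanced_minibatches(fake_samples(5, 0), 4), "both classes")
  expect_error(make_balanced_minibatches(s, 7), "even")
})

test_that("training learns the identity task and reduces L1 loss", {
  co <- cached("fdg_signal_cohort",
               simulate_cohort(20, 20, small_params(seed = 77),
                               atlas = small_atlas()))
  atl <- small_atlas()
  samples <- unlist(lapply(co$studies[c(1:10, 21:30)], extract_slices,
                           atlas = atl, brain_fraction_min = 0.01),
                    recursive = FALSE)
  # identity task: target := input
  samples <- lapply(samples, function(s) {
    s$amyloid_slice <- s$fdg_slice
    s
  })
  cfg <- gan_config_small(epochs = 10L, seed = 11)
  gen <- train_translator(samples, cfg)
  hist <- gen$loss_history
  expect_identical(nrow(hist), 10L)
  expect_lt(hist$gen_l1_loss[10], 0.1)
  expect_lt(hist$gen_l1_loss[10], hist$gen_l1_loss[1])
  expect_true(all(is.finite(unlist(hist[, -1]))))
})

test_that("training is deterministic given the configuration seed", {
  co <- small_cohort()
  atl <- small_atlas()
  samples <- unlist(lapply(co$studies[c(1, 4)], extract_slices, atlas = atl,
                           brain_fraction_min = 0.01), recursive = FALSE)
  cfg <- gan_config_small(epochs = 2L, seed = 21)
  g1 <- train_translator(samples, cfg)
  g2 <- train_translator(samples, cfg)
  expect_identical(g1$loss_history, g2$loss_history)
  expect_identical(g1$weights, g2$weights)
  g3 <- train_translator(samples, gan_config_small(epochs = 2L, seed = 22))
  expect_false(identical(g1$loss_history, g3$loss_history))
})

test_that("volume synthesis restacks slices with zero fill and bounded range", {
  co <- small_cohort()
  atl <- small_atlas()
  samples <- unlist(lapply(co$studies[c(1, 4)], extract_slices, atlas = atl,
                           brain_fraction_min = 0.01), recursive = FALSE)
  gen <- cached("tiny_generator",
                train_translator(samples, gan_config_small(epochs = 2L, seed = 5)))
  fdg <- co$studies[[2]]$fdg
  syn <- synthesize_volume(gen, fdg, atl)
  expect_identical(dim(syn$data), dim(fdg$data))
  frac <- apply(atl$labels != 0L, 3, mean)
  skipped <- which(frac < gen$config$brain_fraction_min)
  expect_true(all(syn$data[, , skipped] == 0))
  expect_true(all(syn$data >= 0))
  expect_true(all(syn$data <= gen$intensity_window[2] + 1e-9))
  # no retained slice: the output volume is all zero
  syn0 <- synthesize_volume(gen, fdg, atl, brain_fraction_min = 1.01)
  expect_true(all(syn0$data == 0))
  # deterministic inference
  syn2 <- synthesize_volume(gen, fdg, atl)
  expect_identical(syn$data, syn2$data)
})

test_that("generator checkpoints round-trip through disk", {
  co <- small_cohort()
  atl <- small_atlas()
  samples <- unlist(lapply(co$studies[c(1, 4)], extract_slices, atlas = atl,
                           brain_fraction_min = 0.01), recursive = FALSE)
  gen <- cached("tiny_generator",
                train_translator(samples, gan_config_small(epochs = 2L, seed = 5)))
  tmp <- withr::local_tempdir()
  path <- file.path(tmp, "gen.rds")
  write_generator(gen, path)
  back <- read_generator(path)
  fdg <- co$studies[[3]]$fdg
  expect_identical(synthesize_volume(back, fdg, atl)$data,
                   synthesize_volume(gen, fdg, atl)$data)
  expect_identical(back$intensity_window, gen$intensity_window)
})
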