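# two well-separated 10-dimensional Gaussian clusters
separable_data <- function(n_per_class = 15, gap = 6, seed = 1) {
  withr::with_seed(seed, {
    pos <- matrix(rnorm(n_per_class * 10, mean = gap), n_per_class, 10)
    neg <- matrix(rnorm(n_per_class * 10, mean = 0), n_per_class, 10)
  })
  list(features = rbind(pos, neg),
       labels = rep(c("positive", "negative"), each = n_per_class))
}

test_that("the Gaussian kernel has its closed-form values and symmetry", {
  u <- c(1, 2, 3)
  expect_identical(gaussian_kernel(u, u, 2), 1)
  v <- u + c(2, 0, 0)  # distance 2 = bandwidth * sqrt(2) at bandwidth sqrt(2)
  expect_equal(gaussian_kernel(u, v, sqrt(2)), exp(-1), tolerance = 1e-12)
  set.seed(8)
  for (rep in 1:5) {
    a <- rnorm(10)
    b <- rnorm(10)
    expect_equal(gaussian_kernel(a, b, 1.3), gaussian_kernel(b, a, 1.3))
    expect_gt(gaussian_kernel(a, b, 1.3), 0)
    expect_lte(gaussian_kernel(a, b, 1.3), 1)
  }
  expect_error(gaussian_kernel(1:3, 1:4, 1), "dimension")
  expect_error(gaussian_kernel(u, u, 0), "bandwidth")
})

test_that("the analytic penalized-likelihood gradient matches finite differences", {
  set.seed(14)
  n <- 12
  X <- matrix(rnorm(n * 10), n, 10)
  y <- rep(c(1, 0), length.out = n)
  K <- petsynth:::kernel_matrix(X, X, 2)
  for (rep in 1:20) {
    theta <- rnorm(n + 1, sd = 0.5)
    ob <- petsynth:::klr_objective(theta, K, y, reg_lambda = 0.05)
    h <- 1e-5
    num <- vapply(seq_len(n + 1), function(i) {
      tp <- theta; tm <- theta
      tp[i] <- tp[i] + h
      tm[i] <- tm[i] - h
      (petsynth:::klr_objective(tp, K, y, 0.05)$value -
         petsynth:::klr_objective(tm, K, y, 0.05)$value) / (2 * h)
    }, numeric(1))
    rel <- max(abs(ob$gradient - num)) / max(1, max(abs(num)))
    expect_lt(rel, 1e-5)
  }
})

test_that("separable clusters are fit perfectly and degenerate limits behave", {
  d <- separable_data()
  model <- klr_fit(d$features, d$labels)
  expect_true(model$converged)
  pred <- klr_classify(model, d$features)
  expect_identical(pred, d$labels)
  p <- predict(model, d$features)
  expect_true(all(p > 0 & p < 1))
  # prediction at a support point lands on the correct side of 0.5
  expect_gt(predict(model, d$features[1, ]), 0.5)
  expect_lt(predict(model, d$features[30, ]), 0.5)

  # all-zero alpha and bias: probability one half everywhere
  null_model <- model
  null_model$alpha[] <- 0
  null_model$bias <- 0
  expect_true(all(predict(null_model, d$features) == 0.5))

  # penalty-dominated limit: intercept-only model predicting the prevalence
  d2 <- separable_data(n_per_class = 10, seed = 2)
  skew_f <- d2$features[c(1:5, 11:20), ]
  skew_l <- d2$labels[c(1:5, 11:20)]  # prevalence 1/3
  big <- klr_fit(skew_f, skew_l, reg_lambda = 1e7)
  expect_lt(max(abs(big$alpha)), 1e-4)
  expect_equal(unname(predict(big, matrix(rnorm(10), 1))), 1 / 3,
               tolerance = 0.01)

  expect_error(klr_fit(d$features, rep("positive", 30)), "both classes")
  expect_error(klr_fit(d$features[1:3, ], d$labels[1:3]), "at least 4")
})

test_that("regularization monotonically worsens the training likelihood", {
  d <- separable_data(n_per_class = 8, gap = 2, seed = 5)
  K <- petsynth:::kernel_matrix(d$features, d$features,
                                median_bandwidth(d$features))
  y <- as.numeric(d$labels == "positive")
  nll_at <- function(lambda) {
    m <- klr_fit(d$features, d$labels, reg_lambda = lambda)
    f <- log(predict(m, d$features) / (1 - predict(m, d$features)))
    -sum(y * f - log1p(exp(f)))
  }
  nlls <- vapply(c(1e-4, 1e-2, 1, 100), nll_at, numeric(1))
  expect_true(all(diff(nlls) >= -1e-6))
})

test_that("stratified k-fold accuracy behaves at the separable and null extremes", {
  d <- separable_data()
  expect_identical(kfold_accuracy(d$features, d$labels, k = 5, seed = 3), 1)

  # stratification: fold sizes differ by at most one per class
  fold <- petsynth:::stratified_folds(d$labels, 5, seed = 9)
  for (cl in c("positive", "negative")) {
    sizes <- table(fold[d$labels == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }

  # permuted labels: chance-level accuracy over seeds
  accs <- vapply(1:10, function(s) {
    withr::with_seed(100 + s, {
      lab <- sample(d$labels)
    })
    kfold_accuracy(d$features, lab, k = 5, seed = s)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)

  expect_error(kfold_accuracy(d$features, d$labels, k = 20), "at least k")
})

test_that("ROC curves match pair counting and behave at the extremes", {
  lab <- rep(c("positive", "negative"), each = 10)
  perfect <- roc_curve(lab, c(rep(2, 10), rep(1, 10)))
  expect_identical(perfect$auc, 1)
  expect_true(all(diff(perfect$curve$sensitivity) >= 0))

  set.seed(19)
  null_lab <- rep(c("positive", "negative"), each = 500)
  null_roc <- roc_curve(null_lab, rnorm(1000))
  expect_lt(abs(null_roc$auc - 0.5), 0.06)

  # exhaustive small fixtures, including ties, against pair counting
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    lab <- sample(rep(c("positive", "negative"), length.out = n))
    if (length(unique(lab)) < 2) next
    sc <- sample(round(rnorm(n), 1))  # rounded: ties occur
    r <- roc_curve(lab, sc)
    expect_equal(r$auc, bf_auc(lab, sc), tolerance = 1e-12)
  }
  expect_error(roc_curve(rep("positive", 5), rnorm(5)), "both classes")
})

test_that("ROC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  lab <- sample(rep(c("positive", "negative"), each = 15))
  sc <- rnorm(30) + (lab == "positive")
  ours <- roc_curve(lab, sc)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = lab, predictor = sc, levels = c("negative", "positive"),
    direction = "<", quiet = TRUE
  )))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("confusion summaries reproduce x/y-style reporting", {
  lab <- rep(c("positive", "negative"), each = 5)
  all_right <- confusion_summary(lab, lab)
  expect_identical(all_right$accuracy, 1)
  expect_identical(all_right$sensitivity, 1)
  expect_identical(all_right$specificity, 1)

  all_neg <- confusion_summary(rep(c("positive", "negative"), each = 40),
                               rep("negative", 80))
  expect_identical(all_neg$sensitivity, 0)
  expect_identical(all_neg$specificity, 1)
  expect_identical(all_neg$accuracy, 0.5)

  # 29 of 40 positives and 39 of 40 negatives correct: accuracy 68/80
  truth <- rep(c("positive", "negative"), each = 40)
  pred <- c(rep("positive", 29), rep("negative", 11),
            rep("negative", 39), rep("positive", 1))
  cs <- confusion_summary(truth, pred)
  expect_equal(cs$accuracy, 68 / 80)
  expect_equal(cs$sensitivity, 29 / 40)
  expect_equal(cs$specificity, 39 / 40)
  expect_identical(cs$correct, 68L)
  expect_error(confusion_summary(lab, lab[-1]), "mismatch")
})
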