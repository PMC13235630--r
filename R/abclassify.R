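#' Gaussian (RBF) kernel
#'
#' `exp(-||u - v||^2 / (2 * bandwidth^2))`, a similarity in (0, 1].
#'
#' @param u,v numeric feature vectors of equal length.
#' @param bandwidth kernel length-scale (> 0).
#'
#' @return Scalar similarity.
#' @export
gaussian_kernel <- function(u, v, bandwidth) {
  if (length(u) != length(v)) stop("dimension mismatch", call. = FALSE)
  if (bandwidth <= 0) stop("bandwidth must be > 0", call. = FALSE)
  exp(-sum((u - v)^2) / (2 * bandwidth^2))
}

# Gaussian kernel matrix between rows of A and rows of B
kernel_matrix <- function(A, B, bandwidth) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * bandwidth^2))
}

#' Median-heuristic kernel bandwidth
#'
#' The median of the pairwise Euclidean distances between training feature
#' vectors, a standard scale-free default for Gaussian kernels.
#'
#' @param features numeric matrix, one row per observation.
#' @return Positive scalar bandwidth.
#' @export
median_bandwidth <- function(features) {
  d <- as.numeric(dist(features))
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) stop("degenerate features", call. = FALSE)
  m
}

# penalized negative log-likelihood and its gradient for the kernel logit
# f = K alpha + bias, penalty (lambda/2) alpha' K alpha. `theta` = c(alpha, b).
klr_objective <- function(theta, K, y, reg_lambda) {
  n <- nrow(K)
  alpha <- theta[seq_len(n)]
  bias <- theta[n + 1]
  f <- as.numeric(K %*% alpha) + bias
  # log(1 + exp(f)) computed stably
  lse <- ifelse(f > 30, f, log1p(exp(pmin(f, 30))))
  nll <- sum(lse - y * f) + reg_lambda / 2 * sum(alpha * (K %*% alpha))
  p <- 1 / (1 + exp(-f))
  grad <- c(as.numeric(K %*% (p - y)) + reg_lambda * as.numeric(K %*% alpha),
            sum(p - y))
  list(value = nll, gradient = grad)
}

#' Fit a Gaussian-kernel logistic-regression amyloid classifier
#'
#' Minimizes the ridge-penalized negative log-likelihood of the kernel
#' expansion logit `f(x) = sum_i alpha_i k(x, x_i) + bias` with penalty
#' `(reg_lambda / 2) * alpha' K alpha`, by full-batch Newton iterations from
#' zero initialization. Fitting is deterministic; convergence is declared
#' when the gradient max-norm falls below `1e-8` (an iteration cap of 100 is
#' reported in the `converged` field if hit).
#'
#' @param features numeric matrix, one row per subject, columns in
#'   [roi_feature_order()] order (any fixed feature set works).
#' @param labels character or factor of `"positive"` / `"negative"`; both
#'   classes must be present and `nrow(features) >= 4`.
#' @param bandwidth Gaussian kernel length-scale; default is the median
#'   heuristic on the training features.
#' @param reg_lambda ridge penalty weight (default 1e-3).
#'
#' @return A `klr_model` with fields `support_features`, `alpha`, `bias`,
#'   `bandwidth`, `reg_lambda`, `feature_order`, `converged`, `iterations`.
#' @export
klr_fit <- function(features, labels, bandwidth = NULL, reg_lambda = 1e-3) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) stop("non-finite features", call. = FALSE)
  labels <- as.character(labels)
  if (!all(labels %in% c("positive", "negative"))) {
    stop("labels must be 'positive' or 'negative'", call. = FALSE)
  }
  y <- as.numeric(labels == "positive")
  n <- nrow(features)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  if (is.null(bandwidth)) bandwidth <- median_bandwidth(features)
  if (bandwidth <= 0 || reg_lambda < 0) {
    stop("bandwidth must be > 0 and reg_lambda >= 0", call. = FALSE)
  }

  K <- kernel_matrix(features, features, bandwidth)
  theta <- numeric(n + 1)
  max_iter <- 100L
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    ob <- klr_objective(theta, K, y, reg_lambda)
    if (max(abs(ob$gradient)) < 1e-8) {
      converged <- TRUE
      break
    }
    alpha <- theta[seq_len(n)]
    f <- as.numeric(K %*% alpha) + theta[n + 1]
    p <- 1 / (1 + exp(-f))
    r <- pmax(p * (1 - p), 1e-12)
    # Hessian blocks: [K R K + lambda K,  K R 1; 1' R K, sum(R)]
    KR <- K * rep(r, each = n)   # K %*% diag(r) (K symmetric)
    H <- rbind(cbind(KR %*% K + reg_lambda * K, KR %*% rep(1, n)),
               c(as.numeric(t(r) %*% K), sum(r)))
    H <- H + diag(1e-10, n + 1)
    step <- tryCatch(solve(H, ob$gradient), error = function(e) {
      solve(H + diag(1e-6, n + 1), ob$gradient)
    })
    # halving line search on the penalized NLL
    t_ls <- 1
    repeat {
      cand <- theta - t_ls * step
      if (klr_objective(cand, K, y, reg_lambda)$value <= ob$value ||
          t_ls < 1e-8) break
      t_ls <- t_ls / 2
    }
    theta <- theta - t_ls * step
  }

  structure(
    list(support_features = features, alpha = theta[seq_len(n)],
         bias = theta[n + 1], bandwidth = bandwidth, reg_lambda = reg_lambda,
         feature_order = colnames(features), converged = converged,
         iterations = iter),
    class = "klr_model"
  )
}

#' @export
print.klr_model <- function(x, ...) {
  cat(sprintf(
    "<klr_model> %d support points, bandwidth %.4g, lambda %.3g (%s in %d it.)\n",
    nrow(x$support_features), x$bandwidth, x$reg_lambda,
    if (x$converged) "converged" else "iteration cap hit", x$iterations
  ))
  invisible(x)
}

#' Predict amyloid-positivity probabilities
#'
#' Logistic of the kernel-expansion logit; the decision rule used throughout
#' labels a case positive when the probability is at least 0.5.
#'
#' @param object a [klr_fit()] model.
#' @param features numeric matrix (or single vector) of new observations with
#'   the training feature dimension.
#' @param ... unused.
#'
#' @return Numeric vector of probabilities of the positive class.
#' @export
predict.klr_model <- function(object, features, ...) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  if (ncol(features) != ncol(object$support_features)) {
    stop("feature dimension mismatch", call. = FALSE)
  }
  Kx <- kernel_matrix(features, object$support_features, object$bandwidth)
  f <- as.numeric(Kx %*% object$alpha) + object$bias
  1 / (1 + exp(-f))
}

#' Predicted class labels
#'
#' @param model a `klr_model`.
#' @param features new observations.
#' @param threshold probability cutoff (default 0.5).
#' @return Character vector of `"positive"` / `"negative"`.
#' @export
klr_classify <- function(model, features, threshold = 0.5) {
  p <- predict(model, features)
  ifelse(p >= threshold, "positive", "negative")
}

#' @describeIn klr_fit broom-style per-support-point coefficients.
#' @param x a `klr_model`.
#' @param ... unused.
#' @method tidy klr_model
#' @export
tidy.klr_model <- function(x, ...) {
  tibble::tibble(term = c(paste0("alpha_", seq_along(x$alpha)), "bias"),
                 estimate = c(x$alpha, x$bias))
}

#' @describeIn klr_fit broom-style one-row model summary.
#' @method glance klr_model
#' @export
glance.klr_model <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$support_features), bandwidth = x$bandwidth,
    reg_lambda = x$reg_lambda, converged = x$converged,
    iterations = x$iterations
  )
}

# stratified fold assignment: class proportions preserved within +/- 1
stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validated classifier accuracy
#'
#' Assigns subjects to `k` stratified folds (class proportions preserved
#' within one subject; seeded assignment), fits the classifier on each
#' training split, and pools held-out predictions into one
#' correct-classification proportion.
#'
#' @inheritParams klr_fit
#' @param k number of folds (>= 2; each class must have at least `k`
#'   members).
#' @param seed fold-assignment seed.
#'
#' @return Pooled held-out accuracy (proportion in `[0, 1]`).
#' @export
kfold_accuracy <- function(features, labels, k = 5L, bandwidth = NULL,
                           reg_lambda = 1e-3, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (min(table(labels)) < k) {
    stop("each class must have at least k members", call. = FALSE)
  }
  fold <- stratified_folds(labels, k, seed)
  pred <- character(length(labels))
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- klr_fit(features[tr, , drop = FALSE], labels[tr],
                     bandwidth = bandwidth, reg_lambda = reg_lambda)
    pred[!tr] <- klr_classify(model, features[!tr, , drop = FALSE])
  }
  mean(pred == labels)
}

#' Receiver-operating-characteristic curve
#'
#' Threshold sweep over the unique scores (descending, with a sentinel above
#' the maximum so the curve starts at sensitivity 0): at each cutoff a case
#' is called positive when its score is >= the cutoff. The AUC is the
#' trapezoidal area, which equals the Mann-Whitney concordant-pair
#' probability with ties counted half.
#'
#' @param labels `"positive"` / `"negative"` per case.
#' @param scores numeric classifier scores (higher = more positive).
#'
#' @return A `roc_result` with a `curve` tibble (`threshold`, `sensitivity`,
#'   `specificity`) and scalar `auc`.
#' @export
roc_curve <- function(labels, scores) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  y <- labels == "positive"
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[y] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!y] < t), numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (head(sens, -1) + sens[-1]) / 2)
  structure(
    list(curve = tibble::tibble(threshold = thr, sensitivity = sens,
                                specificity = spec),
         auc = auc),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f over %d thresholds\n", x$auc,
              nrow(x$curve)))
  invisible(x)
}

#' @describeIn roc_curve the threshold/sensitivity/specificity table.
#' @param x a `roc_result`.
#' @param ... unused.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @describeIn roc_curve one-row summary with the AUC.
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_thresholds = nrow(x$curve))
}

#' Confusion summary of predicted amyloid status
#'
#' Accuracy, sensitivity (`TP / (TP + FN)` w.r.t. the positive class) and
#' specificity as proportions, with the underlying counts retained for
#' "x/y"-style reporting.
#'
#' @param labels true `"positive"` / `"negative"` labels.
#' @param predictions predicted labels of the same length.
#'
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity`,
#'   `correct`, `n`, `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_summary <- function(labels, predictions) {
  labels <- as.character(labels)
  predictions <- as.character(predictions)
  if (length(labels) != length(predictions)) {
    stop("length mismatch", call. = FALSE)
  }
  tp <- sum(labels == "positive" & predictions == "positive")
  fn <- sum(labels == "positive" & predictions == "negative")
  tn <- sum(labels == "negative" & predictions == "negative")
  fp <- sum(labels == "negative" & predictions == "positive")
  tibble::tibble(
    accuracy = (tp + tn) / length(labels),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    correct = tp + tn, n = length(labels),
    tp = tp, fn = fn, tn = tn, fp = fp
  )
}
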