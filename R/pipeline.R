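#' Plan the classifier/translator case allocation
#'
#' Seeded random assignment reproducing the study design: `n_classifier`
#' cases (half per class) are reserved to train the amyloid classifier; the
#' remaining cases are partitioned into `n_folds` class-balanced validation
#' folds whose sizes are even and as equal as possible, so every translator
#' training set (the non-classifier cases minus one validation fold) has even
#' cardinality and equal class counts. For the 110-case design with 30
#' classifier cases and 6 folds this yields validation sizes
#' \{12, 14, 14, 14, 14, 12\} and training sizes of 66 or 68.
#'
#' @param cohort a [pet_cohort()] with equal class counts.
#' @param n_classifier even number of classifier cases (< cohort size).
#' @param n_folds number of cross-validation folds (>= 2).
#' @param seed assignment seed.
#'
#' @return A `split_plan` with `classifier_ids` and `folds` (list of
#'   `list(train, validation)` id vectors).
#' @export
plan_splits <- function(cohort, n_classifier, n_folds, seed = 1L) {
  status <- cohort_status(cohort)
  ids_pos <- names(status)[status == "positive"]
  ids_neg <- names(status)[status == "negative"]
  if (length(ids_pos) != length(ids_neg)) {
    stop("cohort class counts must be equal (", length(ids_pos), " positive vs ",
         length(ids_neg), " negative)", call. = FALSE)
  }
  if (n_classifier %% 2 != 0 || n_classifier >= length(status)) {
    stop("n_classifier must be even and smaller than the cohort", call. = FALSE)
  }
  if (n_folds < 2) stop("n_folds must be >= 2", call. = FALSE)
  n_half <- n_classifier / 2
  rem_per_class <- length(ids_pos) - n_half
  if (rem_per_class < n_folds) {
    stop("infeasible split: ", rem_per_class, " cases per class remain after ",
         "reserving the classifier set, but ", n_folds,
         " folds each need at least one case per class", call. = FALSE)
  }

  withr::with_seed(as.integer(seed), {
    pos <- sample(ids_pos)
    neg <- sample(ids_neg)
  })
  classifier_ids <- c(pos[seq_len(n_half)], neg[seq_len(n_half)])
  pos_rem <- pos[-seq_len(n_half)]
  neg_rem <- neg[-seq_len(n_half)]
  # per-class fold sizes as equal as possible; the validation fold is the
  # union of one positive and one equal-sized negative chunk, so its size is
  # even and every training set (even total minus even fold) is even too
  sizes <- rep(floor(rem_per_class / n_folds), n_folds)
  extra <- rem_per_class - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  all_rem <- c(pos_rem, neg_rem)
  folds <- lapply(seq_len(n_folds), function(f) {
    val <- c(pos_rem[starts[f]:ends[f]], neg_rem[starts[f]:ends[f]])
    list(train = setdiff(all_rem, val), validation = val)
  })
  structure(
    list(classifier_ids = classifier_ids, folds = folds,
         n_folds = n_folds, seed = as.integer(seed)),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  vs <- vapply(x$folds, function(f) length(f$validation), integer(1))
  ts <- vapply(x$folds, function(f) length(f$train), integer(1))
  cat(sprintf(
    "<split_plan> %d classifier cases, %d folds; validation sizes {%s}, training sizes {%s}\n",
    length(x$classifier_ids), x$n_folds,
    paste(vs, collapse = ","), paste(ts, collapse = ",")
  ))
  invisible(x)
}

#' Experiment configuration
#'
#' Bundles every setting of a full cross-validated synthesis experiment. The
#' defaults mirror the full study design (110 cases, 30 classifier cases, 6
#' folds, full-scale translator); [experiment_config_small()] is the
#' CPU-scale profile used in examples and tests (40 cases, 12 classifier
#' cases, 4 folds, 64x64 translator).
#'
#' @param phantom a [phantom_params()] cohort source (or `NULL` when
#'   `manifest` is given).
#' @param manifest optional path to a cohort manifest CSV to load instead of
#'   simulating.
#' @param n_positive,n_negative simulated class sizes (ignored with
#'   `manifest`).
#' @param gan a [gan_config()].
#' @param n_classifier even number of classifier-training cases.
#' @param n_folds translator cross-validation folds.
#' @param classifier_k classifier-validation folds (the generalization check
#'   on the classifier cases).
#' @param bandwidth,reg_lambda classifier hyperparameters (see [klr_fit()]).
#' @param seed master seed for splits and per-fold training seeds.
#'
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(phantom = phantom_params(), manifest = NULL,
                              n_positive = 55L, n_negative = 55L,
                              gan = gan_config(), n_classifier = 30L,
                              n_folds = 6L, classifier_k = 5L,
                              bandwidth = NULL, reg_lambda = 1e-3,
                              seed = 1L) {
  if (n_classifier %% 2 != 0) stop("n_classifier must be even", call. = FALSE)
  if (n_folds < 2) stop("n_folds must be >= 2", call. = FALSE)
  structure(
    list(phantom = phantom, manifest = manifest, n_positive = n_positive,
         n_negative = n_negative, gan = gan, n_classifier = n_classifier,
         n_folds = n_folds, classifier_k = classifier_k,
         bandwidth = bandwidth, reg_lambda = reg_lambda,
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' @rdname experiment_config
#' @param ... overrides passed to [experiment_config()].
#' @export
experiment_config_small <- function(...) {
  args <- list(phantom = phantom_params_small(), n_positive = 20L,
               n_negative = 20L, gan = gan_config_small(),
               n_classifier = 12L, n_folds = 4L)
  args <- utils::modifyList(args, list(...))
  do.call(experiment_config, args)
}

# train-and-synthesize for one fold; translator = "pix2pix" or "oracle"
# (oracle passes the real amyloid volume through, to test the plumbing)
run_fold <- function(cohort, plan, fold_index, config, translator) {
  fold <- plan$folds[[fold_index]]
  by_id <- setNames(cohort$studies, cohort_ids(cohort))
  train_studies <- by_id[fold$train]
  val_studies <- by_id[fold$validation]

  if (translator == "oracle") {
    synth <- lapply(val_studies, function(s) s$amyloid)
    names(synth) <- fold$validation
    return(list(synth = synth, gen = NULL))
  }

  gcfg <- config$gan
  gcfg$seed <- config$seed + fold_index
  samples <- unlist(lapply(train_studies, extract_slices, atlas = cohort$atlas,
                           brain_fraction_min = gcfg$brain_fraction_min),
                    recursive = FALSE)
  gen <- train_translator(samples, gcfg)
  synth <- lapply(val_studies, function(s) {
    synthesize_volume(gen, s$fdg, cohort$atlas)
  })
  names(synth) <- fold$validation
  list(synth = synth, gen = gen)
}

#' Run the full cross-validated synthesis experiment
#'
#' Orchestrates the study design end to end: (1) obtain the cohort (simulate
#' a phantom cohort or load a manifest); (2) plan the classifier/fold splits;
#' (3) fit the amyloid classifier on the real amyloid ROI means of the
#' classifier cases, recording its stratified k-fold accuracy; (4) per fold,
#' train the translator on the training cases' slices, synthesize the
#' validation FDG volumes, run [evaluate_fold()], and classify the real and
#' synthetic validation volumes with the classifier; (5) pool folds into
#' regression tables, Wilcoxon results, per-fold and pooled accuracies, and
#' ROC curves for real and synthetic images.
#'
#' @param config an [experiment_config()].
#' @param translator `"pix2pix"` (the trained network) or `"oracle"` (the
#'   real amyloid volume passed through, for plumbing checks).
#' @param keep_generators keep the trained per-fold generators in the report
#'   (larger object).
#'
#' @return An `experiment_report` list: `classifier_cv_accuracy`,
#'   `fold_evaluations`, `fold_table`, `predictions`, `confusion` (real and
#'   synthetic), `roc` (real and synthetic), `plan`, `config`.
#' @export
run_experiment <- function(config = experiment_config_small(),
                           translator = c("pix2pix", "oracle"),
                           keep_generators = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  translator <- match.arg(translator)

  cohort <- if (!is.null(config$manifest)) {
    read_cohort(config$manifest)
  } else {
    ph <- config$phantom
    ph$seed <- config$seed
    simulate_cohort(config$n_positive, config$n_negative, ph)
  }
  atlas <- cohort$atlas
  status <- cohort_status(cohort)

  plan <- plan_splits(cohort, config$n_classifier, config$n_folds,
                      seed = config$seed)
  # leakage guards: the classifier never sees translator cases and no fold's
  # training set touches its validation set
  for (f in plan$folds) {
    stopifnot(length(intersect(plan$classifier_ids, c(f$train, f$validation))) == 0,
              length(intersect(f$train, f$validation)) == 0)
  }

  by_id <- setNames(cohort$studies, cohort_ids(cohort))
  cls_feats <- t(vapply(by_id[plan$classifier_ids], function(s) {
    roi_feature_vector(s$amyloid, atlas)
  }, numeric(10)))
  cls_labels <- status[plan$classifier_ids]
  cv_acc <- kfold_accuracy(cls_feats, cls_labels, k = config$classifier_k,
                           bandwidth = config$bandwidth,
                           reg_lambda = config$reg_lambda,
                           seed = config$seed)
  classifier <- klr_fit(cls_feats, cls_labels, bandwidth = config$bandwidth,
                        reg_lambda = config$reg_lambda)

  fold_evals <- vector("list", config$n_folds)
  pred_rows <- vector("list", config$n_folds)
  gens <- vector("list", config$n_folds)
  for (f in seq_len(config$n_folds)) {
    res <- tryCatch(
      run_fold(cohort, plan, f, config, translator),
      error = function(e) {
        stop("stage 'translate' failed at fold ", f, ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
    if (keep_generators) gens[[f]] <- res$gen
    val_ids <- plan$folds[[f]]$validation
    val_studies <- by_id[val_ids]
    fold_evals[[f]] <- tryCatch(
      evaluate_fold(val_studies, res$synth, atlas),
      error = function(e) {
        stop("stage 'evaluate' failed at fold ", f, ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
    feats_real <- t(vapply(val_studies, function(s) {
      roi_feature_vector(s$amyloid, atlas)
    }, numeric(10)))
    feats_syn <- t(vapply(val_ids, function(id) {
      roi_feature_vector(res$synth[[id]], atlas)
    }, numeric(10)))
    pred_rows[[f]] <- tibble::tibble(
      fold = f, subject_id = val_ids, status = unname(status[val_ids]),
      prob_real = predict(classifier, feats_real),
      prob_synthetic = predict(classifier, feats_syn)
    )
  }

  predictions <- dplyr::bind_rows(pred_rows)
  predictions$pred_real <- ifelse(predictions$prob_real >= 0.5,
                                  "positive", "negative")
  predictions$pred_synthetic <- ifelse(predictions$prob_synthetic >= 0.5,
                                       "positive", "negative")

  fold_table <- dplyr::bind_rows(lapply(seq_len(config$n_folds), function(f) {
    g <- glance(fold_evals[[f]])
    acc <- dplyr::summarise(
      predictions[predictions$fold == f, ],
      accuracy_real = mean(.data$pred_real == .data$status),
      accuracy_synthetic = mean(.data$pred_synthetic == .data$status)
    )
    dplyr::bind_cols(tibble::tibble(fold = f), g, acc)
  }))

  confusion <- list(
    real = confusion_summary(predictions$status, predictions$pred_real),
    synthetic = confusion_summary(predictions$status, predictions$pred_synthetic)
  )
  roc <- list(
    real = roc_curve(predictions$status, predictions$prob_real),
    synthetic = roc_curve(predictions$status, predictions$prob_synthetic)
  )

  structure(
    list(classifier_cv_accuracy = cv_acc, classifier = classifier,
         fold_evaluations = fold_evals, fold_table = fold_table,
         predictions = predictions, confusion = confusion, roc = roc,
         plan = plan, config = config, translator = translator,
         generators = if (keep_generators) gens else NULL),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf(
    paste0("<experiment_report> %s translator, %d folds\n",
           "  classifier CV accuracy (real): %.3f\n",
           "  pooled accuracy real %.3f / synthetic %.3f; AUC synthetic %.3f\n"),
    x$translator, x$config$n_folds, x$classifier_cv_accuracy,
    x$confusion$real$accuracy, x$confusion$synthetic$accuracy,
    x$roc$synthetic$auc
  ))
  invisible(x)
}

#' @describeIn run_experiment per-fold summary table (regression
#'   coefficients, Wilcoxon p-values, quality metrics, accuracies).
#' @param x an `experiment_report`.
#' @param ... unused.
#' @method tidy experiment_report
#' @export
tidy.experiment_report <- function(x, ...) x$fold_table

#' @describeIn run_experiment one-row pooled summary.
#' @method glance experiment_report
#' @export
glance.experiment_report <- function(x, ...) {
  roi <- dplyr::bind_rows(lapply(x$fold_evaluations, `[[`, "roi"))
  con <- dplyr::bind_rows(lapply(x$fold_evaluations, `[[`, "contrasts"))
  vf <- linear_fit(roi$real, roi$synthetic)
  cf <- linear_fit(con$real, con$synthetic)
  tibble::tibble(
    classifier_cv_accuracy = x$classifier_cv_accuracy,
    accuracy_real = x$confusion$real$accuracy,
    accuracy_synthetic = x$confusion$synthetic$accuracy,
    sensitivity_synthetic = x$confusion$synthetic$sensitivity,
    specificity_synthetic = x$confusion$synthetic$specificity,
    auc_real = x$roc$real$auc, auc_synthetic = x$roc$synthetic$auc,
    pooled_voxel_slope = vf$slope, pooled_voxel_r_squared = vf$r_squared,
    pooled_contrast_slope = cf$slope,
    pooled_contrast_intercept = cf$intercept,
    pooled_contrast_r_squared = cf$r_squared,
    pooled_contrast_p_slope = cf$p_slope,
    mean_ssim = mean(x$fold_table$ssim)
  )
}

#' Write an experiment report to CSV/JSON files
#'
#' Emits the per-fold regression table, per-subject predictions and quality
#' metrics as CSV and a pooled JSON summary into `dir`.
#'
#' @param report an `experiment_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$fold_table, file.path(dir, "fold_table.csv"),
            row.names = FALSE)
  write.csv(report$predictions, file.path(dir, "predictions.csv"),
            row.names = FALSE)
  quality <- dplyr::bind_rows(lapply(seq_along(report$fold_evaluations),
    function(f) {
      dplyr::mutate(report$fold_evaluations[[f]]$quality, fold = f)
    }))
  write.csv(quality, file.path(dir, "quality.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(glance(report)),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
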