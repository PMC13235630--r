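#' Plot a ROC curve
#'
#' @param object a [roc_curve()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  dat <- object$curve
  ggplot2::ggplot(dat, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot real-versus-synthetic contrast with the pooled regression line
#'
#' One point per (subject, region) white/gray contrast pair; the fitted
#' synthetic-on-real regression line is annotated with its equation and r^2.
#'
#' @param object a [evaluate_fold()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot fold_evaluation
#' @export
autoplot.fold_evaluation <- function(object, ...) {
  fit <- object$contrast_fit
  lab <- sprintf("y = %.2fx + %.2f  (r² = %.2f)", fit$slope,
                 fit$intercept, fit$r_squared)
  ggplot2::ggplot(object$contrasts,
                  ggplot2::aes(x = .data$real, y = .data$synthetic,
                               colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept) +
    ggplot2::labs(
      x = "Contrast, real image", y = "Contrast, synthetic image",
      title = "White/gray-matter contrast, real vs synthetic",
      subtitle = lab, colour = "Status"
    ) +
    ggplot2::theme_minimal()
}

#' Plot translator training losses
#'
#' @param object a `trained_generator`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot trained_generator
#' @export
autoplot.trained_generator <- function(object, ...) {
  long <- tidyr::pivot_longer(object$loss_history, -"epoch",
                              names_to = "loss", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~loss, scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = "Mean batch loss",
                  title = "Translator training history") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a volume
#'
#' @param vol a [pet_volume()].
#' @param z axial slice index (default: middle slice).
#' @return A ggplot object.
#' @export
plot_slice <- function(vol, z = NULL) {
  if (is.null(z)) z <- ceiling(dim(vol$data)[3] / 2)
  sl <- vol$data[, , z]
  dat <- tidyr::expand_grid(y = seq_len(ncol(sl)), x = seq_len(nrow(sl)))
  dat$value <- as.numeric(sl)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y,
                                    fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Axial slice %d", z), fill = "Intensity") +
    ggplot2::theme_void()
}
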