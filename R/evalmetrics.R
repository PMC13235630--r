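#' Image quality metrics between a real and a synthetic volume
#'
#' Computes, over the masked voxels: mean squared error; peak signal-to-noise
#' ratio `10*log10(peak^2 / mse)` with `peak` the maximum of the real volume
#' over the mask (`Inf` when `mse` is 0); and the mean structural similarity
#' index. SSIM is computed slice-wise on axial slices with an 11-pixel
#' Gaussian window (sd 1.5, replicate-padded), stability constants
#' `(0.01 L)^2` and `(0.03 L)^2` where `L` is the real volume's dynamic range
#' over the mask, population covariances, and a 5-pixel border exclusion
#' before averaging (the convention of the standard reference
#' implementation).
#'
#' @param real,synth [pet_volume()] objects of equal shape.
#' @param mask logical array of the same shape (e.g. the atlas brain mask);
#'   must be nonempty.
#'
#' @return One-row tibble with columns `mse`, `psnr`, `ssim`.
#' @export
quality_metrics <- function(real, synth, mask) {
  if (!identical(dim(real$data), dim(synth$data))) {
    stop("volume shapes differ", call. = FALSE)
  }
  if (!identical(dim(real$data), dim(mask))) {
    stop("mask shape differs from the volumes", call. = FALSE)
  }
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  rv <- real$data[mask]
  sv <- synth$data[mask]
  mse <- mean((rv - sv)^2)
  peak <- max(rv)
  psnr <- if (mse == 0) Inf else 10 * log10(peak^2 / mse)
  L <- max(rv) - min(rv)
  ssim <- ssim_masked(real$data, synth$data, mask, L)
  tibble::tibble(mse = mse, psnr = psnr, ssim = ssim)
}

# mean SSIM over masked voxels, slice-wise 2D windows; L = dynamic range
ssim_masked <- function(a, b, mask, L, sigma = 1.5, radius = 5L) {
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  nz <- dim(a)[3]
  total <- 0
  count <- 0
  nr <- dim(a)[1]; nc <- dim(a)[2]
  interior <- matrix(FALSE, nr, nc)
  interior[(radius + 1):(nr - radius), (radius + 1):(nc - radius)] <- TRUE
  for (z in seq_len(nz)) {
    m <- mask[, , z] & interior
    if (!any(m)) next
    x <- a[, , z]
    y <- b[, , z]
    ux <- gaussian_blur2d_replicate_cpp(x, sigma, radius)
    uy <- gaussian_blur2d_replicate_cpp(y, sigma, radius)
    uxx <- gaussian_blur2d_replicate_cpp(x * x, sigma, radius)
    uyy <- gaussian_blur2d_replicate_cpp(y * y, sigma, radius)
    uxy <- gaussian_blur2d_replicate_cpp(x * y, sigma, radius)
    vx <- uxx - ux^2
    vy <- uyy - uy^2
    cxy <- uxy - ux * uy
    s <- ((2 * ux * uy + c1) * (2 * cxy + c2)) /
      ((ux^2 + uy^2 + c1) * (vx + vy + c2))
    total <- total + sum(s[m])
    count <- count + sum(m)
  }
  if (count == 0) stop("mask is empty after border exclusion", call. = FALSE)
  total / count
}

#' ROI mean intensities over the ten Centiloid-style regions
#'
#' Mean intensity of each `(group, hemisphere)` gray-matter region, in the
#' fixed order of [roi_feature_order()] (five groups, left then right).
#'
#' @param vol a [pet_volume()].
#' @param atlas a [label_atlas()] on the same grid.
#'
#' @return Tibble with columns `region` (ordered per [roi_feature_order()]),
#'   `group`, `hemisphere`, `mean`; exactly 10 rows.
#' @export
roi_means <- function(vol, atlas) {
  ord <- roi_feature_order()
  gm <- atlas$regions[atlas$regions$tissue == "GM", ]
  rows <- lapply(ord, function(nm) {
    parts <- strsplit(nm, "_(?=[LR]$)", perl = TRUE)[[1]]
    g <- parts[1]; h <- parts[2]
    reg <- gm[gm$group == g & gm$hemisphere == h, ]
    vals <- vol$data[atlas$labels == reg$region_id[1]]
    if (length(vals) == 0) {
      stop("ROI region is empty: ", nm, call. = FALSE)
    }
    tibble::tibble(region = nm, group = g, hemisphere = h, mean = mean(vals))
  })
  dplyr::bind_rows(rows)
}

#' ROI mean feature vector
#'
#' @param vol,atlas see [roi_means()].
#' @return Named numeric vector of 10 ROI means in [roi_feature_order()]
#'   order.
#' @export
roi_feature_vector <- function(vol, atlas) {
  tab <- roi_means(vol, atlas)
  setNames(tab$mean, tab$region)
}

#' White/gray-matter contrast of one region group
#'
#' The contrast statistic `(mu_W - mu_G) / (sigma_W + sigma_G)`, where `mu`
#' and `sigma` are the mean and (population) standard deviation of the
#' white-matter and gray-matter voxels of the group. High in amyloid-negative
#' images (white > gray); falls toward zero in positives as gray-matter
#' signal rises. Invariant under global positive scaling and additive shifts
#' of the volume, and antisymmetric under exchanging the two tissue regions.
#'
#' @param vol a [pet_volume()].
#' @param atlas a [label_atlas()].
#' @param group region group name (e.g. `"frontal_insular"`).
#' @param hemisphere `"L"` or `"R"`.
#'
#' @return One-row tibble: `region_group`, `hemisphere`, `mu_w`, `mu_g`,
#'   `sigma_w`, `sigma_g`, `contrast`.
#' @export
wg_contrast <- function(vol, atlas, group, hemisphere) {
  reg <- atlas$regions
  gid <- reg$region_id[reg$tissue == "GM" & reg$group == group &
                         reg$hemisphere == hemisphere]
  wid <- reg$region_id[reg$tissue == "WM" & reg$group == group &
                         reg$hemisphere == hemisphere]
  if (length(gid) != 1 || length(wid) != 1) {
    stop("no paired GM/WM regions for group ", group, " ", hemisphere,
         call. = FALSE)
  }
  g <- vol$data[atlas$labels == gid]
  w <- vol$data[atlas$labels == wid]
  if (length(g) == 0 || length(w) == 0) {
    stop("empty GM or WM region for group ", group, call. = FALSE)
  }
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  sw <- sd_pop(w); sg <- sd_pop(g)
  if (sw + sg <= 0) {
    stop("degenerate contrast: both regions are constant", call. = FALSE)
  }
  tibble::tibble(
    region_group = group, hemisphere = hemisphere,
    mu_w = mean(w), mu_g = mean(g), sigma_w = sw, sigma_g = sg,
    contrast = (mean(w) - mean(g)) / (sw + sg)
  )
}

#' Contrast records for all ten region groups of a volume
#'
#' @param vol,atlas see [wg_contrast()].
#' @return Tibble with one [wg_contrast()] row per `(group, hemisphere)`.
#' @export
contrast_table <- function(vol, atlas) {
  ord <- roi_feature_order()
  dplyr::bind_rows(lapply(ord, function(nm) {
    parts <- strsplit(nm, "_(?=[LR]$)", perl = TRUE)[[1]]
    wg_contrast(vol, atlas, parts[1], parts[2])
  }))
}

#' Ordinary least-squares line fit
#'
#' Simple linear regression of `y` on `x` with `r^2` (squared Pearson
#' correlation), two-sided t-based p-value for the slope, and 95% confidence
#' intervals for slope and intercept.
#'
#' @param x,y numeric vectors of equal length >= 3; `x` must not be constant.
#'
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `slope_lo`,
#'   `slope_hi`, `intercept_lo`, `intercept_hi`, `p_slope`, `n`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (sd(x) == 0) stop("x is constant", call. = FALSE)
  fit <- lm(y ~ x)
  ci <- suppressWarnings(confint(fit, level = 0.95))
  # perfect fits (e.g. oracle identity synthesis) trigger a benign precision
  # warning from summary.lm
  sm <- suppressWarnings(summary(fit))
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = suppressWarnings(stats::cor(x, y))^2,
    slope_lo = ci[2, 1], slope_hi = ci[2, 2],
    intercept_lo = ci[1, 1], intercept_hi = ci[1, 2],
    p_slope = unname(sm$coefficients[2, 4]),
    n = length(x)
  )
}

#' One-sided Wilcoxon rank-sum test
#'
#' Tests the alternative that values in `a` tend to be greater than values in
#' `b`. The null distribution is enumerated exactly when `length(a) +
#' length(b) <= 12` and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param a,b numeric vectors (nonempty).
#'
#' @return The p-value.
#' @export
wilcoxon_onesided <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty input", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b)) <= 12 && !ties
  suppressWarnings(
    wilcox.test(a, b, alternative = "greater", exact = exact,
                correct = TRUE)$p.value
  )
}

#' Evaluate one cross-validation fold of synthetic volumes
#'
#' The four-domain comparison between matched real and synthetic amyloid
#' volumes of one validation fold:
#' \itemize{
#' \item per-subject image quality ([quality_metrics()] over the brain mask);
#' \item voxel-value regression: synthetic-on-real OLS pooled over the 10
#'   ROI means of all fold subjects;
#' \item contrast regression: synthetic-on-real OLS pooled over all
#'   `(subject, region)` white/gray contrasts;
#' \item one-sided Wilcoxon tests that amyloid-negative subjects have greater
#'   mean contrast than positives, separately for real and synthetic images
#'   (one value per subject: the mean contrast over the 10 regions).
#' }
#'
#' @param real_studies list of [paired_study()] objects (the fold's
#'   validation cases).
#' @param synth_volumes named list of synthetic amyloid [pet_volume()]s,
#'   names matching the study subject ids.
#' @param atlas a [label_atlas()].
#'
#' @return A `fold_evaluation` list with tibbles `quality`, `roi`,
#'   `contrasts`, `voxel_fit`, `contrast_fit`, and `wilcoxon`.
#' @export
evaluate_fold <- function(real_studies, synth_volumes, atlas) {
  ids <- vapply(real_studies, function(s) s$subject_id, character(1))
  if (!setequal(ids, names(synth_volumes)) || anyDuplicated(ids)) {
    stop("subject ids of real studies and synthetic volumes do not match",
         call. = FALSE)
  }
  mask <- atlas$labels != 0L

  per_subject <- lapply(real_studies, function(s) {
    synth <- synth_volumes[[s$subject_id]]
    q <- quality_metrics(s$amyloid, synth, mask)
    roi_r <- roi_means(s$amyloid, atlas)
    roi_s <- roi_means(synth, atlas)
    con_r <- contrast_table(s$amyloid, atlas)
    con_s <- contrast_table(synth, atlas)
    list(
      quality = dplyr::mutate(q, subject_id = s$subject_id, status = s$status,
                              .before = 1),
      roi = tibble::tibble(
        subject_id = s$subject_id, status = s$status, region = roi_r$region,
        real = roi_r$mean, synthetic = roi_s$mean
      ),
      contrasts = tibble::tibble(
        subject_id = s$subject_id, status = s$status,
        region = paste0(con_r$region_group, "_", con_r$hemisphere),
        real = con_r$contrast, synthetic = con_s$contrast
      )
    )
  })

  quality <- dplyr::bind_rows(lapply(per_subject, `[[`, "quality"))
  roi <- dplyr::bind_rows(lapply(per_subject, `[[`, "roi"))
  contrasts <- dplyr::bind_rows(lapply(per_subject, `[[`, "contrasts"))

  voxel_fit <- linear_fit(roi$real, roi$synthetic)
  contrast_fit <- linear_fit(contrasts$real, contrasts$synthetic)

  subj_contrast <- dplyr::summarise(
    dplyr::group_by(contrasts, .data$subject_id, .data$status),
    real = mean(.data$real), synthetic = mean(.data$synthetic),
    .groups = "drop"
  )
  wilcox <- tibble::tibble(
    image = c("real", "synthetic"),
    p_value = c(
      wilcoxon_onesided(subj_contrast$real[subj_contrast$status == "negative"],
                        subj_contrast$real[subj_contrast$status == "positive"]),
      wilcoxon_onesided(
        subj_contrast$synthetic[subj_contrast$status == "negative"],
        subj_contrast$synthetic[subj_contrast$status == "positive"]
      )
    )
  )

  structure(
    list(quality = quality, roi = roi, contrasts = contrasts,
         voxel_fit = voxel_fit, contrast_fit = contrast_fit,
         wilcoxon = wilcox),
    class = "fold_evaluation"
  )
}

#' @export
print.fold_evaluation <- function(x, ...) {
  cat(sprintf(
    paste0("<fold_evaluation> %d subjects | voxel fit slope %.3f (r2 %.3f) | ",
           "contrast fit slope %.3f (r2 %.3f) | ssim %.3f\n"),
    nrow(x$quality), x$voxel_fit$slope, x$voxel_fit$r_squared,
    x$contrast_fit$slope, x$contrast_fit$r_squared, mean(x$quality$ssim)
  ))
  invisible(x)
}

#' @describeIn evaluate_fold per-subject quality/ROI/contrast rows in one
#'   long tibble.
#' @param x a `fold_evaluation`.
#' @param ... unused.
#' @method tidy fold_evaluation
#' @export
tidy.fold_evaluation <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidyr::pivot_longer(x$roi, c("real", "synthetic"),
                                      names_to = "image"),
                  measure = "roi_mean"),
    dplyr::mutate(tidyr::pivot_longer(x$contrasts, c("real", "synthetic"),
                                      names_to = "image"),
                  measure = "contrast")
  )
}

#' @describeIn evaluate_fold one-row fold summary (fit coefficients, Wilcoxon
#'   p-values, mean quality metrics).
#' @method glance fold_evaluation
#' @export
glance.fold_evaluation <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$quality),
    voxel_slope = x$voxel_fit$slope,
    voxel_intercept = x$voxel_fit$intercept,
    voxel_r_squared = x$voxel_fit$r_squared,
    contrast_slope = x$contrast_fit$slope,
    contrast_intercept = x$contrast_fit$intercept,
    contrast_r_squared = x$contrast_fit$r_squared,
    contrast_p_slope = x$contrast_fit$p_slope,
    wilcoxon_p_real = x$wilcoxon$p_value[x$wilcoxon$image == "real"],
    wilcoxon_p_synthetic = x$wilcoxon$p_value[x$wilcoxon$image == "synthetic"],
    mse = mean(x$quality$mse), psnr = mean(x$quality$psnr),
    ssim = mean(x$quality$ssim)
  )
}
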