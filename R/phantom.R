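#' Phantom cohort parameters
#'
#' Settings of the digital paired FDG/amyloid brain phantom. Intensities are
#' unitless uptake values prior to reference normalization. The defaults
#' encode the physiology the downstream statistics assume: FDG gray matter
#' uptake well above white matter; amyloid white matter above gray matter in
#' negatives (nondisplaceable binding) with gray matter rising to the white
#' matter level in positives; and, in positives, FDG hypometabolism in
#' posterior cingulate/precuneus and parietal gray matter so that amyloid
#' status is recoverable from the FDG image at all.
#'
#' @param grid integer length-3 grid size; the canonical grid is
#'   `c(128, 128, 60)`.
#' @param spacing voxel spacing in mm (default 1.5 mm isotropic).
#' @param fdg_gm_mean,fdg_wm_mean,fdg_ref_mean FDG uptake means for gray
#'   matter, white matter and the cerebellar reference region.
#' @param amy_wm_mean amyloid white matter uptake mean.
#' @param amy_gm_mean_negative,amy_gm_mean_positive amyloid gray matter means
#'   by status.
#' @param amy_ref_mean amyloid uptake in the reference region.
#' @param hypometabolism_factor multiplicative FDG reduction applied to
#'   pcc_precuneus and parietal gray matter in positives (in (0, 1]).
#' @param subject_sd standard deviation of the per-subject log-normal global
#'   scale factor.
#' @param region_jitter half-width of the uniform per-region multiplicative
#'   jitter (0.05 = +/-5 percent).
#' @param noise_sd additive Gaussian noise SD (uptake units, pre-normalization).
#' @param psf_fwhm_mm full width at half maximum of the Gaussian
#'   point-spread-function blur, mm.
#' @param seed master seed for cohort simulation.
#'
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(grid = c(128L, 128L, 60L),
                           spacing = c(1.5, 1.5, 1.5),
                           fdg_gm_mean = 3.0, fdg_wm_mean = 1.0,
                           fdg_ref_mean = 2.0,
                           amy_wm_mean = 2.0,
                           amy_gm_mean_negative = 1.0,
                           amy_gm_mean_positive = 2.0,
                           amy_ref_mean = 1.0,
                           hypometabolism_factor = 0.8,
                           subject_sd = 0.1,
                           region_jitter = 0.05,
                           noise_sd = 0.1,
                           psf_fwhm_mm = 6.0,
                           seed = 1L) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3L, all(grid >= 32L))
  means <- c(fdg_gm_mean, fdg_wm_mean, fdg_ref_mean, amy_wm_mean,
             amy_gm_mean_negative, amy_gm_mean_positive, amy_ref_mean)
  if (any(means <= 0)) stop("all uptake means must be > 0", call. = FALSE)
  if (hypometabolism_factor <= 0 || hypometabolism_factor > 1) {
    stop("hypometabolism_factor must be in (0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(grid = grid, spacing = as.numeric(spacing),
         fdg_gm_mean = fdg_gm_mean, fdg_wm_mean = fdg_wm_mean,
         fdg_ref_mean = fdg_ref_mean, amy_wm_mean = amy_wm_mean,
         amy_gm_mean_negative = amy_gm_mean_negative,
         amy_gm_mean_positive = amy_gm_mean_positive,
         amy_ref_mean = amy_ref_mean,
         hypometabolism_factor = hypometabolism_factor,
         subject_sd = subject_sd, region_jitter = region_jitter,
         noise_sd = noise_sd, psf_fwhm_mm = psf_fwhm_mm,
         seed = as.integer(seed)),
    class = "phantom_params"
  )
}

#' Scaled-down phantom parameters
#'
#' A 64x64x32 grid at 3 mm spacing covering the same physical extent as the
#' canonical 128x128x60 grid at 1.5 mm, for CPU-scale experiments. About 27 of
#' the 32 axial slices contain brain.
#'
#' @param ... overrides passed to [phantom_params()].
#' @return A `phantom_params` list.
#' @export
phantom_params_small <- function(...) {
  args <- list(grid = c(64L, 64L, 32L), spacing = c(3, 3, 3))
  args <- utils::modifyList(args, list(...))
  do.call(phantom_params, args)
}

#' Build the phantom label atlas
#'
#' Constructs a nested-ellipsoid brain on the parameter grid: a white matter
#' core inside a gray matter ribbon, with in-plane ellipse radii following a
#' profile that peaks mid-volume so roughly five sixths of the axial slices
#' contain brain (about 50 of 60 on the canonical grid). The lowest brain
#' slices form a cerebellar reference region; the remaining brain is split
#' into left/right hemispheres and five anatomical groups (frontal_insular,
#' temporal, parietal, pcc_precuneus, striatum) by position along the y and z
#' axes, applied to gray and white matter alike so every gray matter group
#' has a paired white matter region. Labels 1-10 are GM, 11-20 the paired WM
#' (GM id + 10), 21 the reference; a `wholebrain` pseudo-region (id 99,
#' absent from the map) denotes all brain voxels.
#'
#' @param params a [phantom_params()] object.
#'
#' @return A [label_atlas()].
#' @export
make_atlas <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  nx <- params$grid[1]; ny <- params$grid[2]; nz <- params$grid[3]
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2; cz <- (nz - 1) / 2
  zh <- 0.845 * nz / 2  # brain spans ~84.5% of the axial extent
  rz <- sqrt(pmax(0, 1 - ((seq_len(nz) - 1 - cz) / zh)^2))

  x <- seq_len(nx) - 1
  y <- seq_len(ny) - 1
  labels <- array(0L, dim = c(nx, ny, nz))
  ax0 <- 0.42 * nx; by0 <- 0.45 * ny
  gm_frac <- 0.70  # WM core radius as a fraction of the outer radius

  brain_z <- which(rz > 0 & ax0 * rz >= 0.5 & by0 * rz >= 0.5)
  if (length(brain_z) < 8) stop("grid too small to host all regions", call. = FALSE)
  n_ref <- max(3L, round(0.12 * length(brain_z)))
  ref_z <- brain_z[seq_len(n_ref)]
  rest_z <- setdiff(brain_z, ref_z)
  z_mid <- rest_z[ceiling(length(rest_z) / 2)]

  group_of <- function(vnorm, upper_z) {
    # vnorm in [-1, 1] along y (anterior < 0); z halves split four groups
    ifelse(vnorm < -1 / 3, "frontal_insular",
      ifelse(vnorm <= 1 / 3,
        ifelse(upper_z, "parietal", "temporal"),
        ifelse(upper_z, "pcc_precuneus", "striatum")
      )
    )
  }
  groups <- c("frontal_insular", "temporal", "parietal", "pcc_precuneus",
              "striatum")

  xm <- matrix(x, nx, ny)
  ym <- matrix(y, nx, ny, byrow = TRUE)
  for (z in brain_z) {
    ax <- ax0 * rz[z]; by <- by0 * rz[z]
    rho <- ((xm - cx) / ax)^2 + ((ym - cy) / by)^2
    inside <- rho <= 1
    if (!any(inside)) next
    if (z %in% ref_z) {
      sl <- matrix(0L, nx, ny)
      sl[inside] <- 21L
      labels[, , z] <- sl
      next
    }
    wm <- rho <= gm_frac^2
    gm <- inside & !wm
    vnorm <- (ym - cy) / by
    grp <- group_of(vnorm, upper_z = z >= z_mid)
    hemi_r <- xm > cx
    gi <- match(grp, groups)                  # 1..5
    base <- (gi - 1L) * 2L + ifelse(hemi_r, 2L, 1L)  # GM ids 1..10
    sl <- matrix(0L, nx, ny)
    sl[gm] <- base[gm]
    sl[wm] <- base[wm] + 10L
    labels[, , z] <- sl
  }

  hemi <- rep(c("L", "R"), times = 5)
  grp_rep <- rep(groups, each = 2)
  regions <- tibble::tibble(
    region_id = c(1:10, 11:20, 21L, 99L),
    name = c(paste0(grp_rep, "_", hemi, "_GM"),
             paste0(grp_rep, "_", hemi, "_WM"),
             "reference", "wholebrain"),
    tissue = c(rep("GM", 10), rep("WM", 10), "reference", "wholebrain"),
    hemisphere = c(hemi, hemi, NA, NA),
    group = c(grp_rep, grp_rep, "reference", "other")
  )
  # all 21 real labels must be nonempty on this grid
  counts <- tabulate(labels[labels != 0L], nbins = 21L)
  if (any(counts == 0L)) {
    stop("grid too small to host all regions", call. = FALSE)
  }
  label_atlas(labels, regions, spacing = params$spacing)
}

#' Simulate one paired FDG/amyloid phantom subject
#'
#' Builds piecewise-constant FDG and amyloid uptake maps from the atlas and
#' the parameter means (positives receive the FDG hypometabolism factor in
#' pcc_precuneus and parietal gray matter and the elevated amyloid gray
#' matter mean), applies per-region multiplicative jitter, a per-subject
#' log-normal global scale, Gaussian PSF blur, additive Gaussian noise and a
#' floor at zero, then normalizes FDG by the whole-brain mean and amyloid by
#' the reference-region mean. Deterministic given `(status, params, seed)`.
#'
#' @param atlas a [label_atlas()] from [make_atlas()].
#' @param status `"positive"` or `"negative"`.
#' @param params a [phantom_params()] object.
#' @param seed integer seed for this subject.
#' @param subject_id identifier stored in the volumes.
#'
#' @return A [paired_study()].
#' @export
simulate_subject <- function(atlas, status, params = phantom_params(),
                             seed = 1L, subject_id = "S001") {
  stopifnot(inherits(atlas, "label_atlas"))
  status <- match.arg(status, c("positive", "negative"))
  labs <- atlas$labels
  nlab <- 21L

  fdg_mean <- numeric(nlab)
  amy_mean <- numeric(nlab)
  reg <- atlas$regions[atlas$regions$region_id <= nlab, ]
  for (i in seq_len(nrow(reg))) {
    id <- reg$region_id[i]
    fdg_mean[id] <- switch(reg$tissue[i],
      GM = params$fdg_gm_mean, WM = params$fdg_wm_mean,
      reference = params$fdg_ref_mean)
    amy_mean[id] <- switch(reg$tissue[i],
      GM = if (status == "positive") params$amy_gm_mean_positive
           else params$amy_gm_mean_negative,
      WM = params$amy_wm_mean,
      reference = params$amy_ref_mean)
    if (status == "positive" && reg$tissue[i] == "GM" &&
        reg$group[i] %in% c("pcc_precuneus", "parietal")) {
      fdg_mean[id] <- fdg_mean[id] * params$hypometabolism_factor
    }
  }

  withr::with_seed(as.integer(seed), {
    jit_f <- runif(nlab, 1 - params$region_jitter, 1 + params$region_jitter)
    jit_a <- runif(nlab, 1 - params$region_jitter, 1 + params$region_jitter)
    scale_f <- exp(rnorm(1, 0, params$subject_sd))
    scale_a <- exp(rnorm(1, 0, params$subject_sd))
    sigma_vox <- (params$psf_fwhm_mm / 2.3548) / params$spacing

    build <- function(means, jit, gscale) {
      img <- array(0, dim = dim(labs))
      nz <- labs != 0L
      img[nz] <- gscale * (means * jit)[labs[nz]]
      if (params$psf_fwhm_mm > 0) {
        img <- gaussian_blur3d_cpp(img, sigma_vox)
      }
      if (params$noise_sd > 0) {
        img <- img + array(rnorm(length(img), 0, params$noise_sd), dim = dim(img))
      }
      img[img < 0] <- 0
      pet_volume(array(img, dim = dim(labs)), spacing = params$spacing,
                 subject_id = subject_id)
    }
    fdg <- build(fdg_mean, jit_f, scale_f)
    amy <- build(amy_mean, jit_a, scale_a)
  })

  fdg <- normalize_by_reference(fdg, atlas, "wholebrain")
  amy <- normalize_by_reference(amy, atlas, "reference")
  paired_study(subject_id, status, fdg, amy)
}

#' Simulate a paired phantom cohort
#'
#' Subjects are labelled `P001..` (positive) and `N001..` (negative);
#' per-subject seeds are derived deterministically from `params$seed`, so an
#' identical parameter set reproduces the cohort exactly.
#'
#' @param n_positive,n_negative subject counts per class (>= 1).
#' @param params a [phantom_params()] object.
#' @param atlas optionally, a precomputed [make_atlas()] result.
#'
#' @return A [pet_cohort()].
#' @export
simulate_cohort <- function(n_positive, n_negative,
                            params = phantom_params(), atlas = NULL) {
  stopifnot(n_positive >= 1, n_negative >= 1)
  if (is.null(atlas)) atlas <- make_atlas(params)
  status <- c(rep("positive", n_positive), rep("negative", n_negative))
  ids <- c(sprintf("P%03d", seq_len(n_positive)),
           sprintf("N%03d", seq_len(n_negative)))
  studies <- lapply(seq_along(ids), function(i) {
    seed_i <- (params$seed %% 100000L) * 10007L + i * 7919L
    simulate_subject(atlas, status[i], params,
                     seed = seed_i %% 2147483647L, subject_id = ids[i])
  })
  pet_cohort(studies, atlas)
}
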