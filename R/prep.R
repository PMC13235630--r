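#' Normalize a volume by a reference region mean
#'
#' Divides every voxel by the mean intensity over the named atlas region
#' (SUVR-style scaling): whole brain for FDG, cerebellar reference for
#' amyloid. The output's mean over the reference region is exactly 1, and the
#' operation is idempotent and invariant to global positive rescaling of the
#' input.
#'
#' @param vol a [pet_volume()].
#' @param atlas a [label_atlas()] on the same grid.
#' @param region_name region name in the atlas table (e.g. `"wholebrain"`,
#'   `"reference"`).
#'
#' @return A normalized [pet_volume()].
#' @export
normalize_by_reference <- function(vol, atlas, region_name) {
  vals <- region_values(vol, atlas, region_name)
  if (length(vals) == 0) {
    stop("region '", region_name, "' is empty", call. = FALSE)
  }
  m <- mean(vals)
  if (!is.finite(m) || m <= 0) {
    stop("nonpositive mean over region '", region_name, "'", call. = FALSE)
  }
  pet_volume(vol$data / m, spacing = vol$spacing, subject_id = vol$subject_id)
}

#' Resample a volume onto a target grid
#'
#' Trilinear, edge-clamped resampling onto `target` voxels spanning the same
#' physical extent as the input (voxel spacing rescales accordingly). An
#' input already on the target grid is returned voxelwise unchanged.
#'
#' @param vol a [pet_volume()].
#' @param target integer length-3 target grid size, each dimension >= 2.
#'
#' @return A [pet_volume()] of shape `target`.
#' @export
conform_grid <- function(vol, target) {
  target <- as.integer(target)
  if (length(target) != 3L || any(target < 2L)) {
    stop("`target` must be three integers >= 2", call. = FALSE)
  }
  d <- dim(vol$data)
  if (identical(d, target)) return(vol)
  out <- resample_trilinear_cpp(vol$data, target[1], target[2], target[3])
  new_spacing <- vol$spacing * d / target
  pet_volume(array(out, dim = target), spacing = new_spacing,
             subject_id = vol$subject_id)
}

#' Extract brain-covering axial slice samples from a paired study
#'
#' Returns one sample per axial (z) slice whose brain-voxel fraction (from
#' the atlas label map) is at least `brain_fraction_min`, in ascending z. On
#' the canonical 128x128x60 phantom about 50 of the 60 slices are retained,
#' so an 80-case training set yields more than 3,000 2D training pairs.
#'
#' @param study a [paired_study()] (or a [pet_volume()] for inference-time
#'   extraction without an amyloid target).
#' @param atlas a [label_atlas()] on the same grid.
#' @param brain_fraction_min minimum fraction of in-plane voxels that must be
#'   brain for a slice to be retained (default 0.01).
#'
#' @return A list of `slice_sample` objects with fields `fdg_slice`,
#'   `amyloid_slice` (NULL at inference), `subject_id`, `z_index` (1-based),
#'   `status`.
#' @export
extract_slices <- function(study, atlas, brain_fraction_min = 0.01) {
  if (inherits(study, "pet_volume")) {
    fdg <- study
    amy <- NULL
    status <- NA_character_
    sid <- study$subject_id
  } else {
    stopifnot(inherits(study, "paired_study"))
    fdg <- study$fdg
    amy <- study$amyloid
    status <- study$status
    sid <- study$subject_id
  }
  d <- dim(fdg$data)
  if (!identical(d, dim(atlas$labels))) {
    stop("volume and atlas grids differ", call. = FALSE)
  }
  frac <- apply(atlas$labels != 0L, 3, mean)
  keep <- which(frac >= brain_fraction_min)
  if (length(keep) == 0) {
    stop("no slice reaches brain fraction ", brain_fraction_min, call. = FALSE)
  }
  lapply(keep, function(z) {
    structure(
      list(fdg_slice = fdg$data[, , z],
           amyloid_slice = if (is.null(amy)) NULL else amy$data[, , z],
           subject_id = sid, z_index = z, status = status),
      class = "slice_sample"
    )
  })
}

#' Affine intensity scaling to and from the GAN value range
#'
#' `to_gan_range()` maps `[lo, hi]` linearly onto `[-1, 1]`, clipping values
#' outside the window; `from_gan_range()` inverts the map exactly for
#' in-range values. The window is computed once from the training set and
#' stored with the trained generator so inference uses the same scaling.
#'
#' @param x numeric vector, matrix or array of intensities (or GAN-range
#'   values for the inverse).
#' @param lo,hi window bounds, `hi > lo`.
#'
#' @return Object of the same shape as `x`.
#' @export
to_gan_range <- function(x, lo, hi) {
  if (!(hi > lo)) stop("`hi` must exceed `lo`", call. = FALSE)
  y <- 2 * (x - lo) / (hi - lo) - 1
  y[y < -1] <- -1
  y[y > 1] <- 1
  y
}

#' @rdname to_gan_range
#' @export
from_gan_range <- function(x, lo, hi) {
  if (!(hi > lo)) stop("`hi` must exceed `lo`", call. = FALSE)
  x[x < -1] <- -1
  x[x > 1] <- 1
  (x + 1) / 2 * (hi - lo) + lo
}
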