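#' PET volume objects
#'
#' A `pet_volume` carries a 3D intensity grid in stored voxel space: the first
#' two array dimensions are the in-plane (x, y) axes and the third is the
#' axial/body (z) axis, so `vol$data[, , k]` is the k-th axial slice. Voxel
#' spacing is in millimetres. Volumes are used as-is; no reorientation or
#' registration is attempted.
#'
#' @param data numeric 3D array of finite intensities.
#' @param spacing numeric length-3 vector of positive voxel sizes (mm).
#' @param subject_id optional subject identifier.
#'
#' @return A `pet_volume` object.
#' @export
#' @examples
#' v <- pet_volume(array(1, c(8, 8, 4)), spacing = c(2, 2, 2))
#' dim(v$data)
pet_volume <- function(data, spacing = c(1.5, 1.5, 1.5), subject_id = "") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("volume intensities must all be finite", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive numbers (mm)", call. = FALSE)
  }
  structure(
    list(data = data, spacing = spacing, subject_id = as.character(subject_id)),
    class = "pet_volume"
  )
}

#' @export
print.pet_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<pet_volume> %dx%dx%d voxels, %.3gx%.3gx%.3g mm%s\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    if (nzchar(x$subject_id)) paste0(", subject ", x$subject_id) else ""
  ))
  invisible(x)
}

#' @export
dim.pet_volume <- function(x) dim(x$data)

#' Read a 3D volume from a NIfTI-1 file
#'
#' @param path path to a NIfTI file holding a 3D image.
#' @param subject_id optional subject identifier attached to the volume.
#'
#' @return A [pet_volume()].
#' @export
read_volume <- function(path, subject_id = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop("expected a 3D image, got ", length(d), "D: ", path, call. = FALSE)
  }
  data <- array(as.numeric(img), dim = d)
  if (!all(is.finite(data))) {
    stop("non-finite voxels in ", path, call. = FALSE)
  }
  pet_volume(data, spacing = RNifti::pixdim(img)[1:3], subject_id = subject_id)
}

#' Write a volume to a NIfTI-1 file
#'
#' Intensities are stored as 32-bit floats; PET dynamic range is modest and
#' this halves file size relative to doubles.
#'
#' @param vol a [pet_volume()].
#' @param path destination file path (`.nii` or `.nii.gz`).
#'
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "pet_volume"))
  dat <- vol$data
  attr(dat, "pixdim") <- vol$spacing
  img <- RNifti::asNifti(dat, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Label atlas objects
#'
#' A `label_atlas` pairs an integer region map (same grid as the volumes it
#' annotates; 0 = background) with a region table describing each label:
#' tissue class (`GM`, `WM`, `reference`, `wholebrain`), hemisphere
#' (`L`/`R`/`NA`) and anatomical group (`frontal_insular`, `temporal`,
#' `parietal`, `pcc_precuneus`, `striatum`, `reference`, `other`). The ten
#' `(group, hemisphere)` gray-matter entries form the Centiloid-style feature
#' set used throughout; each group has a paired white-matter region for the
#' white/gray contrast. The `wholebrain` entry is a pseudo-region: its id does
#' not occur in the label map and lookups resolve it as all nonzero labels.
#'
#' @param labels integer 3D array of region ids.
#' @param regions data frame with columns `region_id`, `name`, `tissue`,
#'   `hemisphere`, `group`.
#' @param spacing voxel spacing (mm).
#'
#' @return A `label_atlas` object.
#' @export
label_atlas <- function(labels, regions, spacing = c(1.5, 1.5, 1.5)) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("`labels` must be a 3D array", call. = FALSE)
  }
  regions <- tibble::as_tibble(regions)
  need <- c("region_id", "name", "tissue", "hemisphere", "group")
  if (!all(need %in% names(regions))) {
    stop("region table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  present <- sort(unique(as.integer(labels)))
  present <- present[present != 0L]
  missing <- setdiff(present, regions$region_id)
  if (length(missing) > 0) {
    stop("label map contains ids absent from the region table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  gm <- regions[regions$tissue == "GM", ]
  if (nrow(gm) != 10L || nrow(unique(gm[, c("group", "hemisphere")])) != 10L) {
    stop("atlas must define exactly 10 (group, hemisphere) GM regions",
         call. = FALSE)
  }
  for (i in seq_len(nrow(gm))) {
    wm <- regions[regions$tissue == "WM" &
                    regions$group == gm$group[i] &
                    regions$hemisphere == gm$hemisphere[i], ]
    if (nrow(wm) == 0) {
      stop("GM region ", gm$name[i], " has no paired WM region", call. = FALSE)
    }
  }
  structure(
    list(labels = labels, regions = regions, spacing = as.numeric(spacing)),
    class = "label_atlas"
  )
}

#' @export
print.label_atlas <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_atlas> %dx%dx%d voxels, %d regions\n",
              d[1], d[2], d[3], nrow(x$regions)))
  invisible(x)
}

#' Fixed ROI feature order
#'
#' The documented order of the ten Centiloid-style gray-matter regions used
#' for ROI-mean features: five groups (frontal_insular, temporal, parietal,
#' pcc_precuneus, striatum), left hemisphere then right within each group.
#'
#' @return Character vector of ten `group_hemisphere` names.
#' @export
roi_feature_order <- function() {
  groups <- c("frontal_insular", "temporal", "parietal", "pcc_precuneus",
              "striatum")
  as.vector(t(outer(groups, c("L", "R"), paste, sep = "_")))
}

# logical mask of voxels belonging to a region (tissue/group/hemisphere query)
region_mask <- function(atlas, region_id = NULL, tissue = NULL, group = NULL,
                        hemisphere = NULL) {
  reg <- atlas$regions
  if (!is.null(region_id)) reg <- reg[reg$region_id %in% region_id, ]
  if (!is.null(tissue)) reg <- reg[reg$tissue %in% tissue, ]
  if (!is.null(group)) reg <- reg[reg$group %in% group, ]
  if (!is.null(hemisphere)) reg <- reg[reg$hemisphere %in% hemisphere, ]
  if (nrow(reg) == 1 && reg$tissue[1] == "wholebrain") {
    return(atlas$labels != 0L)
  }
  array(atlas$labels %in% reg$region_id, dim = dim(atlas$labels))
}

# voxel values of a named region; region_name matches regions$name, or
# "wholebrain"
region_values <- function(vol, atlas, region_name) {
  reg <- atlas$regions[atlas$regions$name == region_name, ]
  if (nrow(reg) == 0) {
    stop("unknown region: ", region_name, call. = FALSE)
  }
  if (reg$tissue[1] == "wholebrain") {
    return(vol$data[atlas$labels != 0L])
  }
  vol$data[atlas$labels == reg$region_id[1]]
}

#' Paired FDG/amyloid study
#'
#' One subject's co-registered FDG and amyloid volumes plus amyloid (Abeta)
#' status.
#'
#' @param subject_id subject identifier.
#' @param status `"positive"` or `"negative"` amyloid status.
#' @param fdg,amyloid [pet_volume()] objects on a common grid.
#' @param scanner_id optional scanner identifier.
#'
#' @return A `paired_study` object.
#' @export
paired_study <- function(subject_id, status, fdg, amyloid, scanner_id = "sim") {
  status <- match.arg(status, c("positive", "negative"))
  stopifnot(inherits(fdg, "pet_volume"), inherits(amyloid, "pet_volume"))
  if (!identical(dim(fdg$data), dim(amyloid$data)) ||
      !isTRUE(all.equal(fdg$spacing, amyloid$spacing))) {
    stop("fdg and amyloid volumes must share shape and spacing", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), status = status, fdg = fdg,
         amyloid = amyloid, scanner_id = as.character(scanner_id)),
    class = "paired_study"
  )
}

#' Cohort of paired studies
#'
#' @param studies list of [paired_study()] objects.
#' @param atlas a [label_atlas()] on the same grid as the study volumes.
#'
#' @return A `pet_cohort` object.
#' @export
pet_cohort <- function(studies, atlas) {
  stopifnot(inherits(atlas, "label_atlas"))
  ids <- vapply(studies, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate subject ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  for (s in studies) {
    if (!identical(dim(s$fdg$data), dim(atlas$labels))) {
      stop("volume shape of subject ", s$subject_id,
           " does not match the atlas", call. = FALSE)
    }
  }
  structure(list(studies = studies, atlas = atlas), class = "pet_cohort")
}

#' @export
print.pet_cohort <- function(x, ...) {
  st <- cohort_status(x)
  cat(sprintf("<pet_cohort> %d studies (%d positive / %d negative)\n",
              length(x$studies), sum(st == "positive"), sum(st == "negative")))
  invisible(x)
}

#' @export
length.pet_cohort <- function(x) length(x$studies)

#' Subject ids and statuses of a cohort
#'
#' @param cohort a [pet_cohort()].
#' @return `cohort_ids()`: character vector; `cohort_status()`: named
#'   character vector of statuses.
#' @export
cohort_ids <- function(cohort) {
  vapply(cohort$studies, function(s) s$subject_id, character(1))
}

#' @rdname cohort_ids
#' @export
cohort_status <- function(cohort) {
  setNames(vapply(cohort$studies, function(s) s$status, character(1)),
           cohort_ids(cohort))
}

#' Write a cohort to disk
#'
#' Writes one NIfTI volume per modality per subject, the atlas label map as
#' NIfTI, the region table as JSON, and a CSV manifest (columns `subject_id`,
#' `status`, `fdg_path`, `amyloid_path`, `scanner_id`) with a sidecar JSON
#' naming the atlas files.
#'
#' @param cohort a [pet_cohort()].
#' @param dir output directory (created if missing).
#'
#' @return Path to the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$studies, function(s) {
    fp <- file.path(dir, paste0(s$subject_id, "_fdg.nii.gz"))
    ap <- file.path(dir, paste0(s$subject_id, "_amyloid.nii.gz"))
    write_volume(s$fdg, fp)
    write_volume(s$amyloid, ap)
    data.frame(subject_id = s$subject_id, status = s$status,
               fdg_path = basename(fp), amyloid_path = basename(ap),
               scanner_id = s$scanner_id, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  atlas_nii <- file.path(dir, "atlas_labels.nii.gz")
  lab <- cohort$atlas$labels + 0L
  attr(lab, "pixdim") <- cohort$atlas$spacing
  RNifti::writeNifti(RNifti::asNifti(lab), atlas_nii)
  jsonlite::write_json(cohort$atlas$regions, file.path(dir, "atlas_regions.json"),
                       dataframe = "rows")
  jsonlite::write_json(
    list(atlas_labels = "atlas_labels.nii.gz",
         atlas_regions = "atlas_regions.json"),
    file.path(dir, "manifest.json"), auto_unbox = TRUE
  )
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from a manifest
#'
#' Inverse of [write_cohort()]: loads every study listed in the CSV manifest
#' together with the atlas named in the sidecar `manifest.json`.
#'
#' @param manifest path to the manifest CSV.
#'
#' @return A [pet_cohort()].
#' @export
read_cohort <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest, call. = FALSE)
  dir <- dirname(manifest)
  tab <- read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("subject_id", "status", "fdg_path", "amyloid_path", "scanner_id")
  if (!all(need %in% names(tab))) {
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(tab$status), c("positive", "negative"))
  if (length(bad) > 0) {
    stop("unknown status value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  side <- jsonlite::read_json(file.path(dir, "manifest.json"))
  lab_img <- RNifti::readNifti(file.path(dir, side$atlas_labels))
  labels <- array(as.integer(lab_img), dim = dim(lab_img))
  regions <- jsonlite::fromJSON(file.path(dir, side$atlas_regions))
  atlas <- label_atlas(labels, regions, spacing = RNifti::pixdim(lab_img)[1:3])
  studies <- lapply(seq_len(nrow(tab)), function(i) {
    paired_study(
      tab$subject_id[i], tab$status[i],
      read_volume(file.path(dir, tab$fdg_path[i]), tab$subject_id[i]),
      read_volume(file.path(dir, tab$amyloid_path[i]), tab$subject_id[i]),
      tab$scanner_id[i]
    )
  })
  pet_cohort(studies, atlas)
}
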