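#' 3D scalar volume with voxel spacing
#'
#' Lightweight container for a single-subject anatomical volume: a 3D numeric
#' array of intensities plus the voxel size in millimetres along each axis.
#' Intensities must be finite; the pipeline assumes the volume and its
#' parcellation mask live on the same (already-resampled) grid.
#'
#' @param data 3D numeric array of voxel intensities.
#' @param spacing Numeric length-3 vector, voxel size per axis (mm).
#' @return A `voxel_volume` object.
#' @export
#' @examples
#' vol <- voxel_volume(array(rnorm(27), dim = c(3, 3, 3)))
voxel_volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    rlang::abort("`data` must be a 3D array.")
  }
  if (!all(is.finite(data))) {
    rlang::abort("All voxel intensities must be finite.")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    rlang::abort("`spacing` must be 3 positive voxel sizes (mm).")
  }
  structure(list(data = data, spacing = spacing), class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf(
    "<voxel_volume> %s voxels, spacing %s mm\n",
    paste(dim(x$data), collapse = "x"),
    paste(format(x$spacing), collapse = "x")
  ))
  invisible(x)
}

#' Integer parcellation mask with a label lookup
#'
#' Pairs a 3D integer label map with a lookup table mapping each label id to
#' a hemisphere (`lh`/`rh`) and an anatomical region name, in the style of a
#' FreeSurfer white-matter parcellation (wmparc). Label 0 is background.
#'
#' @param labels 3D integer array; 0 marks background.
#' @param lookup Data frame with columns `label_id`, `hemisphere`, `region`.
#' @return A `parcellation_mask` object. The lookup is stored as a tibble
#'   with an extra `roi` column `"{hemisphere}_{region}"`.
#' @export
parcellation_mask <- function(labels, lookup) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    rlang::abort("`labels` must be a 3D array.")
  }
  lookup <- tibble::as_tibble(lookup)
  required <- c("label_id", "hemisphere", "region")
  if (!all(required %in% names(lookup))) {
    rlang::abort("`lookup` needs columns label_id, hemisphere, region.")
  }
  if (anyDuplicated(lookup$label_id)) {
    rlang::abort("Duplicate label ids in lookup.")
  }
  if (!all(lookup$hemisphere %in% c("lh", "rh"))) {
    rlang::abort("hemisphere must be 'lh' or 'rh'.")
  }
  present <- setdiff(unique(as.integer(labels)), 0L)
  missing <- setdiff(present, lookup$label_id)
  if (length(missing)) {
    rlang::abort(sprintf(
      "Labels present in mask but absent from lookup: %s",
      paste(missing, collapse = ", ")
    ))
  }
  lookup$roi <- paste(lookup$hemisphere, lookup$region, sep = "_")
  structure(
    list(labels = labels, lookup = lookup),
    class = "parcellation_mask"
  )
}

#' @export
print.parcellation_mask <- function(x, ...) {
  cat(sprintf(
    "<parcellation_mask> %s voxels, %d labelled ROIs\n",
    paste(dim(x$labels), collapse = "x"), nrow(x$lookup)
  ))
  invisible(x)
}

#' Read and write volumes and masks as NIfTI-1
#'
#' Thin wrappers over RNifti. Masks are stored as integer NIfTI images with
#' the label lookup in a companion CSV (`label_id,hemisphere,region`).
#'
#' @param x A `voxel_volume` or `parcellation_mask`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param lookup_path Companion CSV path for the mask lookup.
#' @return `read_volume_nifti()` a `voxel_volume`; `read_mask_nifti()` a
#'   `parcellation_mask`; writers return `path` invisibly.
#' @name nifti_io
NULL

#' @rdname nifti_io
#' @export
write_volume_nifti <- function(x, path) {
  stopifnot(inherits(x, "voxel_volume"))
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  voxel_volume(array(as.numeric(img), dim = dim(img)),
               spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname nifti_io
#' @export
write_mask_nifti <- function(x, path, lookup_path) {
  stopifnot(inherits(x, "parcellation_mask"))
  img <- RNifti::asNifti(array(as.integer(x$labels), dim = dim(x$labels)))
  RNifti::writeNifti(img, path, datatype = "int16")
  readr::write_csv(
    x$lookup[, c("label_id", "hemisphere", "region")], lookup_path
  )
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_mask_nifti <- function(path, lookup_path) {
  img <- RNifti::readNifti(path)
  lookup <- readr::read_csv(lookup_path, show_col_types = FALSE)
  parcellation_mask(array(as.integer(img), dim = dim(img)), lookup)
}
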