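#' Extract the 86-feature radiomic profile of one ROI
#'
#' Discretizes the ROI and computes all five families: 16 first-order, 24
#' GLCM, 16 GLRLM, 14 GLDM, 16 GLSZM. Names carry the family prefix, e.g.
#' `glrlm_RunLengthNonUniformity`.
#'
#' @param volume A [voxel_volume()].
#' @param mask A [parcellation_mask()].
#' @param label_id Label to extract.
#' @param bin_width,bin_count Discretization, see [discretize_roi()].
#' @param distance GLCM pair distance (voxels).
#' @param alpha GLDM level tolerance.
#' @return Named numeric vector of length 86.
#' @export
extract_roi_features <- function(volume, mask, label_id, bin_width = 25,
                                 bin_count = NULL, distance = 1L,
                                 alpha = 0) {
  roi <- discretize_roi(volume, mask, label_id, bin_width, bin_count)
  fam <- list(
    firstorder = first_order_features(roi),
    glcm = glcm_features(roi, distance),
    glrlm = glrlm_features(roi),
    gldm = gldm_features(roi, alpha, distance),
    glszm = glszm_features(roi)
  )
  out <- unlist(lapply(names(fam), function(f) {
    stats::setNames(fam[[f]], paste(f, names(fam[[f]]), sep = "_"))
  }))
  if (any(!is.finite(out))) {
    rlang::abort("Non-finite feature value; degenerate-ROI policy failed.")
  }
  out
}

#' Extract the full radiomic feature vector of one subject
#'
#' Runs [extract_roi_features()] over every ROI in the mask lookup and
#' concatenates with the naming convention
#' `{hemi}_{region}_{family}_{feature}` — 86 features per ROI, 5,848 for the
#' standard 68-ROI white-matter parcellation.
#'
#' @inheritParams extract_roi_features
#' @param rois Optional character vector restricting extraction to these
#'   `{hemi}_{region}` names; all must exist in the mask.
#' @return Named numeric vector of length `86 * n_rois`.
#' @export
extract_subject <- function(volume, mask, bin_width = 25, bin_count = NULL,
                            distance = 1L, alpha = 0, rois = NULL) {
  lookup <- mask$lookup
  if (!is.null(rois)) {
    missing <- setdiff(rois, lookup$roi)
    if (length(missing)) {
      rlang::abort(sprintf(
        "ROIs not present in mask lookup: %s", paste(missing, collapse = ", ")
      ))
    }
    lookup <- lookup[lookup$roi %in% rois, ]
  }
  present <- unique(as.integer(mask$labels))
  absent <- setdiff(lookup$label_id, present)
  if (length(absent)) {
    rlang::abort(sprintf(
      "Configured labels missing from mask voxels: %s",
      paste(absent, collapse = ", ")
    ))
  }
  pieces <- lapply(seq_len(nrow(lookup)), function(r) {
    v <- extract_roi_features(volume, mask, lookup$label_id[r], bin_width,
                              bin_count, distance, alpha)
    stats::setNames(v, paste(lookup$roi[r], names(v), sep = "_"))
  })
  unlist(pieces)
}

#' Extract the feature table of a whole cohort
#'
#' One row per subject: `subject_id`, `group`, the clinical scores, and all
#' radiomic features. This is the wide table the correlation filter and the
#' classifier consume.
#'
#' @param cohort A `ppa_cohort` from [generate_cohort()].
#' @inheritParams extract_roi_features
#' @param clinical Include the clinical columns (default `TRUE`).
#' @return Tibble with `attr(., "radiomic_features")` naming the radiomic
#'   columns and `attr(., "extraction_settings")` recording discretization
#'   and texture settings.
#' @export
extract_features <- function(cohort, bin_width = 25, bin_count = NULL,
                             distance = 1L, alpha = 0, clinical = TRUE) {
  stopifnot(inherits(cohort, "ppa_cohort"))
  rows <- lapply(cohort$volumes, function(v) {
    extract_subject(v, cohort$mask, bin_width, bin_count, distance, alpha)
  })
  mat <- do.call(rbind, rows)
  rad <- tibble::as_tibble(mat)
  base <- if (clinical) {
    cohort$clinical
  } else {
    cohort$clinical[, c("subject_id", "group")]
  }
  out <- dplyr::bind_cols(base, rad)
  attr(out, "radiomic_features") <- colnames(mat)
  attr(out, "extraction_settings") <- list(
    binning = if (is.null(bin_count)) {
      list(type = "fixed_width", bin_width = bin_width)
    } else {
      list(type = "fixed_count", bin_count = bin_count)
    },
    glcm_distance = distance, gldm_alpha = alpha,
    directions = "13 unique 3D offsets, distance 1, symmetric, feature-averaged"
  )
  out
}

#' Write a feature table to disk
#'
#' Writes the wide CSV (one row per subject), a long TSV
#' (`subject,roi,family,feature,value`) and a JSON sidecar with the
#' extraction settings.
#'
#' @param features Tibble from [extract_features()].
#' @param dir Output directory.
#' @param stem File stem (default `"features"`).
#' @return `dir`, invisibly.
#' @export
write_feature_table <- function(features, dir, stem = "features") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(features, file.path(dir, paste0(stem, ".csv")))
  rad <- attr(features, "radiomic_features")
  long <- features |>
    dplyr::select(dplyr::all_of(c("subject_id", rad))) |>
    tidyr::pivot_longer(-"subject_id", names_to = "name",
                        values_to = "value") |>
    tidyr::separate_wider_regex(
      "name",
      patterns = c(hemi = "^[lr]h", "_", region = ".+", "_",
                   family = "firstorder|glcm|glrlm|gldm|glszm", "_",
                   feature = "[^_]+$")
    ) |>
    dplyr::mutate(roi = paste(.data$hemi, .data$region, sep = "_")) |>
    dplyr::select("subject_id", "roi", "family", "feature", "value")
  readr::write_tsv(long, file.path(dir, paste0(stem, "_long.tsv")))
  jsonlite::write_json(attr(features, "extraction_settings"),
                       file.path(dir, paste0(stem, "_settings.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
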