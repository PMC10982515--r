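#' Iterative pairwise-correlation redundancy filter
#'
#' Removes redundant features by the iterative procedure used for radiomic
#' feature selection: repeatedly (1) find the feature pair with the highest
#' absolute Pearson correlation; (2) stop once that maximum drops below the
#' cutoff; (3) otherwise drop, of the two, the feature with the higher mean
#' absolute correlation against all currently retained features (excluding
#' itself, including its partner). Ties — equal maximal pairs or equal mean
#' correlations — are broken by original column order: the earlier pair
#' wins, the later column is removed, making the result deterministic.
#' Zero-variance columns (correlation undefined) are removed up front with a
#' warning. The filter is intended to be fitted on the training split only
#' and then applied to held-out data.
#'
#' @param data Data frame whose numeric feature columns are filtered.
#' @param cutoff Correlation threshold in (0, 1]; the default 0.9 removes
#'   every feature pair with `|r| >= 0.9`.
#' @param exclude Column names never entered into the filter (ids, labels,
#'   and — when only radiomics should be filtered — the clinical columns).
#' @return A `ppa_corr_filter`: list with `retained` (ordered names),
#'   `removed` (tibble `step, feature, partner, pair_abs_r, mean_abs_r`),
#'   `zero_variance`, and `cutoff`.
#' @export
#' @examples
#' d <- tibble::tibble(A = rnorm(30))
#' d$B <- d$A + rnorm(30, sd = 0.05)  # |r| > 0.9 with A
#' d$C <- rnorm(30)
#' iterative_correlation_filter(d, cutoff = 0.9, exclude = NULL)
iterative_correlation_filter <- function(data, cutoff = 0.9,
                                         exclude = c("subject_id", "group")) {
  if (cutoff <= 0 || cutoff > 1) rlang::abort("`cutoff` must be in (0, 1].")
  feats <- setdiff(names(data), exclude)
  feats <- feats[vapply(data[feats], is.numeric, TRUE)]
  if (length(feats) < 2) rlang::abort("Need at least 2 feature columns.")
  x <- as.matrix(data[feats])
  if (nrow(x) < 2) rlang::abort("Need at least 2 subjects.")
  if (anyNA(x)) rlang::abort("Feature table contains missing values.")

  sds <- apply(x, 2, stats::sd)
  zero_var <- feats[sds == 0]
  if (length(zero_var)) {
    rlang::warn(sprintf(
      "Removing %d zero-variance feature(s) before filtering.",
      length(zero_var)
    ))
  }
  keep <- feats[sds > 0]
  cmat <- abs(stats::cor(x[, keep, drop = FALSE]))
  diag(cmat) <- NA
  removed <- list()
  step <- 0L
  while (length(keep) >= 2) {
    mx <- max(cmat, na.rm = TRUE)
    if (mx < cutoff) break
    step <- step + 1L
    # earliest pair (by column order) attaining the maximum
    hit <- which(cmat == mx, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    a <- hit[1, 1]
    b <- hit[1, 2]
    mean_r <- rowMeans(cmat[c(a, b), , drop = FALSE], na.rm = TRUE)
    drop_i <- if (mean_r[2] >= mean_r[1]) b else a  # tie: later column goes
    keep_i <- if (drop_i == b) a else b
    removed[[step]] <- tibble::tibble(
      step = step, feature = keep[drop_i], partner = keep[keep_i],
      pair_abs_r = mx, mean_abs_r = unname(mean_r[if (drop_i == b) 2 else 1])
    )
    keep <- keep[-drop_i]
    cmat <- cmat[-drop_i, -drop_i, drop = FALSE]
  }
  structure(
    list(
      retained = keep,
      removed = if (length(removed)) {
        dplyr::bind_rows(removed)
      } else {
        tibble::tibble(step = integer(), feature = character(),
                       partner = character(), pair_abs_r = double(),
                       mean_abs_r = double())
      },
      zero_variance = zero_var,
      cutoff = cutoff
    ),
    class = "ppa_corr_filter"
  )
}

#' @export
print.ppa_corr_filter <- function(x, ...) {
  cat(sprintf(
    "<ppa_corr_filter> cutoff %.2f: retained %d, removed %d (+%d zero-variance)\n",
    x$cutoff, length(x$retained), nrow(x$removed), length(x$zero_variance)
  ))
  invisible(x)
}

#' Apply a fitted correlation filter to a feature table
#'
#' Keeps the retained feature columns (and any non-filtered columns such as
#' ids and labels), so a filter fitted on the training split can be applied
#' to the test split.
#'
#' @param data Data frame to subset.
#' @param filter A `ppa_corr_filter`.
#' @return Tibble with the retained features only.
#' @export
apply_filter <- function(data, filter) {
  stopifnot(inherits(filter, "ppa_corr_filter"))
  drop <- c(filter$removed$feature, filter$zero_variance)
  tibble::as_tibble(data[, setdiff(names(data), drop), drop = FALSE])
}

#' Serialize a correlation-filter result to JSON
#'
#' @param filter A `ppa_corr_filter`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_filter_json <- function(filter, path) {
  jsonlite::write_json(
    list(cutoff = filter$cutoff, retained = filter$retained,
         removed = filter$removed, zero_variance = filter$zero_variance),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
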