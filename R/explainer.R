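#' Shapley additive attributions for a tuned tree ensemble
#'
#' Computes exact tree-path-conditional Shapley values (TreeSHAP) on the raw
#' margin (log-odds) scale, the native additive scale of the ensemble, so
#' for every sample `base_value + sum(attributions) = margin(sample)`.
#' Attributions are conventionally computed on the training split, matching
#' how the model's feature impact is assessed; pass the test split
#' explicitly to attribute held-out samples.
#'
#' @param model A `ppa_model` from [tune_classifier()].
#' @param data Tibble containing the model's feature columns (and ideally
#'   `subject_id` for row names).
#' @return A `ppa_shap`: `shap` matrix (samples x features, log-odds units),
#'   `base_value`, `feature_values` matrix, and `ranking` — a tibble
#'   `rank, feature, mean_abs_shap, direction` where direction is the sign
#'   of the feature-value/attribution association.
#' @export
shapley_attributions <- function(model, data) {
  stopifnot(inherits(model, "ppa_model"))
  extra <- setdiff(
    setdiff(names(data)[vapply(data, is.numeric, TRUE)],
            c("subject_id", model$label_col)),
    model$features
  )
  missing <- setdiff(model$features, names(data))
  if (length(missing) || length(extra)) {
    rlang::abort(sprintf(
      "Feature mismatch. Missing: %s. Extra: %s.",
      if (length(missing)) paste(missing, collapse = ", ") else "none",
      if (length(extra)) paste(extra, collapse = ", ") else "none"
    ))
  }
  contrib <- predict(model, data, type = "contrib")
  bias_col <- intersect(c("BIAS", "(Intercept)"), colnames(contrib))[1]
  base_value <- unname(contrib[1, bias_col])
  shap <- contrib[, setdiff(colnames(contrib), bias_col), drop = FALSE]
  if ("subject_id" %in% names(data)) {
    rownames(shap) <- data$subject_id
  }
  xmat <- feature_matrix(data, model$features)
  direction <- vapply(seq_len(ncol(shap)), function(k) {
    if (stats::sd(xmat[, k]) == 0 || stats::sd(shap[, k]) == 0) {
      return(0)
    }
    sign(stats::cor(xmat[, k], shap[, k]))
  }, 0)
  ranking <- tibble::tibble(
    feature = colnames(shap),
    mean_abs_shap = colMeans(abs(shap)),
    direction = direction
  ) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_shap)) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", "feature", "mean_abs_shap", "direction")
  structure(
    list(shap = shap, base_value = base_value, feature_values = xmat,
         ranking = ranking, positive_class = model$positive_class),
    class = "ppa_shap"
  )
}

#' @export
print.ppa_shap <- function(x, ...) {
  cat(sprintf("<ppa_shap> %d samples x %d features, base value %.4f\n",
              nrow(x$shap), ncol(x$shap), x$base_value))
  print(utils::head(x$ranking, 5))
  invisible(x)
}

#' Beeswarm plot of Shapley attributions
#'
#' The standard SHAP summary: the `top_k` features by mean absolute
#' attribution, one jittered point per sample, colored by the sample's
#' feature-value rank (blue low, red high). Jitter is seeded so the layout
#' is deterministic.
#'
#' @param object A `ppa_shap`.
#' @param top_k Number of features shown (clipped to the feature count with
#'   a warning).
#' @param seed Seed for the jitter layout.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppa_shap
#' @export
autoplot.ppa_shap <- function(object, top_k = 20, seed = 1L, ...) {
  if (top_k > ncol(object$shap)) {
    rlang::warn("`top_k` exceeds the feature count; clipping.")
    top_k <- ncol(object$shap)
  }
  feats <- object$ranking$feature[seq_len(top_k)]
  df <- purrr::map_dfr(feats, function(f) {
    v <- object$feature_values[, f]
    tibble::tibble(
      feature = f, shap = object$shap[, f],
      value_rank = if (stats::sd(v) > 0) rank(v) / length(v) else 0.5
    )
  })
  df$feature <- factor(df$feature, levels = rev(feats))
  set.seed(seed)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$shap, y = .data$feature,
                                   color = .data$value_rank)) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3, color = "grey60") +
    ggplot2::geom_jitter(height = 0.2, width = 0, size = 1, alpha = 0.8) +
    ggplot2::scale_color_gradient(low = "#2166ac", high = "#b2182b",
                                  name = "feature value\n(rank)") +
    ggplot2::labs(
      x = "SHAP value (log-odds)", y = NULL,
      title = sprintf("Feature impact on predicting %s",
                      object$positive_class)
    ) +
    ggplot2::theme_minimal()
}

#' Export the attribution summary: beeswarm figure plus ranked table
#'
#' Writes the beeswarm of the `top_k` features and a CSV ranked table
#' (`rank,feature,mean_abs_shap,direction`), and the full attribution matrix
#' as TSV.
#'
#' @param report A `ppa_shap`.
#' @param dir Output directory.
#' @param stem File stem.
#' @param top_k Features shown in the figure.
#' @param device Figure format, `"png"` or `"svg"`.
#' @return Named character vector of the written paths, invisibly.
#' @export
export_beeswarm <- function(report, dir, stem = "shap", top_k = 20,
                            device = c("png", "svg")) {
  stopifnot(inherits(report, "ppa_shap"))
  device <- match.arg(device)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fig <- file.path(dir, paste0(stem, "_beeswarm.", device))
  p <- ggplot2::autoplot(report, top_k = min(top_k, ncol(report$shap)))
  ggplot2::ggsave(fig, p, width = 7, height = 5, dpi = 150)
  tab <- file.path(dir, paste0(stem, "_ranking.csv"))
  readr::write_csv(report$ranking, tab)
  mat <- file.path(dir, paste0(stem, "_values.tsv"))
  readr::write_tsv(
    dplyr::bind_cols(
      tibble::tibble(subject_id = rownames(report$shap) %||%
                       as.character(seq_len(nrow(report$shap)))),
      tibble::as_tibble(report$shap)
    ),
    mat
  )
  invisible(c(figure = fig, ranking = tab, values = mat))
}
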