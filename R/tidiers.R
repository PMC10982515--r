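#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the cross-validation results of a tuned model
#'
#' @param x A `ppa_model`.
#' @param ... Unused.
#' @return Tibble with one row per sampled hyperparameter candidate and its
#'   mean cross-validated AUC-ROC.
#' @method tidy ppa_model
#' @export
tidy.ppa_model <- function(x, ...) {
  x$cv_results
}

#' One-row summary of a tuned model
#'
#' @param x A `ppa_model`.
#' @param ... Unused.
#' @return Tibble: positive class, feature count, the chosen
#'   hyperparameters and the winning candidate's CV AUC.
#' @method glance ppa_model
#' @export
glance.ppa_model <- function(x, ...) {
  tibble::tibble(
    positive_class = x$positive_class,
    n_features = length(x$features),
    learning_rate = x$best_params$learning_rate,
    max_depth = x$best_params$max_depth,
    n_estimators = x$best_params$n_estimators,
    subsample = x$best_params$subsample,
    lambda = x$best_params$lambda,
    alpha = x$best_params$alpha,
    cv_auc = max(x$cv_results$mean_cv_auc)
  )
}

#' Tidy an evaluation report
#'
#' @param x A `ppa_metrics`.
#' @param ... Unused.
#' @return One-row tibble of the six test metrics plus confusion counts.
#' @method tidy ppa_metrics
#' @export
tidy.ppa_metrics <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(positive_class = x$positive_class),
    x$metrics,
    tibble::as_tibble(as.list(x$confusion))
  )
}

#' Tidy a Shapley attribution report
#'
#' @param x A `ppa_shap`.
#' @param ... Unused.
#' @return The ranking tibble (`rank, feature, mean_abs_shap, direction`).
#' @method tidy ppa_shap
#' @export
tidy.ppa_shap <- function(x, ...) {
  x$ranking
}

#' Tidy a correlation-filter result
#'
#' @param x A `ppa_corr_filter`.
#' @param ... Unused.
#' @return The removal log, one row per eliminated feature.
#' @method tidy ppa_corr_filter
#' @export
tidy.ppa_corr_filter <- function(x, ...) {
  x$removed
}

#' One-row summary of a correlation-filter result
#'
#' @param x A `ppa_corr_filter`.
#' @param ... Unused.
#' @return Tibble: cutoff and retained/removed/zero-variance counts.
#' @method glance ppa_corr_filter
#' @export
glance.ppa_corr_filter <- function(x, ...) {
  tibble::tibble(
    cutoff = x$cutoff, n_retained = length(x$retained),
    n_removed = nrow(x$removed), n_zero_variance = length(x$zero_variance)
  )
}

#' Tidy an experiment: the test metrics table
#'
#' @param x A `ppa_experiment`.
#' @param ... Unused.
#' @return The summary tibble, one row per contrast x feature set.
#' @method tidy ppa_experiment
#' @export
tidy.ppa_experiment <- function(x, ...) {
  x$summary
}

#' Tidy a cohort-statistics report
#'
#' @param x A `ppa_cohort_stats`.
#' @param ... Unused.
#' @return The omnibus test tibble.
#' @method tidy ppa_cohort_stats
#' @export
tidy.ppa_cohort_stats <- function(x, ...) {
  x$tests
}
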