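clinical_score_cols <- function() {
  c("age", "sex", "education", "cdr", "cdr_language", "fluency_animal",
    "fluency_dwords", "bnt")
}

default_positive <- function(pair) {
  if ("HC" %in% pair) setdiff(pair, "HC") else if ("nfvPPA" %in% pair) {
    "nfvPPA"
  } else {
    pair[2]
  }
}

#' Run the full classification experiment
#'
#' For each binary contrast (default: HC vs svPPA, HC vs nfvPPA, svPPA vs
#' nfvPPA) and each feature set (clinical-only and clinical + radiomics):
#' stratified 70:30 split; for the radiomics set, the iterative correlation
#' filter fitted on the training split only; randomized hyperparameter
#' search with stratified cross-validation on the training split; six-metric
#' evaluation on the held-out test split; Shapley attribution of the
#' training samples. The clinical-only set skips the filter stage. All
#' stages derive their seeds from `seed`, so a rerun with the same seed is
#' identical.
#'
#' @param features Wide tibble from [extract_features()] (or any table with
#'   `subject_id`, `group`, clinical columns and feature columns).
#' @param contrasts List of length-2 character vectors of group labels.
#' @param feature_sets Subset of `c("clinical", "clinical_radiomics")`.
#' @param positive_class Optional named character vector mapping contrast
#'   names (`"A_vs_B"`) to the positive label; by default the patient group
#'   (or nfvPPA for the patient-vs-patient contrast).
#' @param train_fraction,cutoff,space Stage parameters: split fraction,
#'   correlation cutoff, [hp_space()].
#' @param filter_clinical Should clinical columns enter the correlation
#'   filter alongside radiomics (default `TRUE`, joint filtering)? If
#'   `FALSE` only radiomic columns are filtered and all clinical columns are
#'   kept.
#' @param seed Master seed.
#' @return A `ppa_experiment`: per contrast x feature set, the fitted
#'   filter (or `NULL`), `ppa_model`, `ppa_metrics` and `ppa_shap`, plus a
#'   `summary` tibble of the test metrics.
#' @export
run_experiment <- function(features,
                           contrasts = list(c("HC", "svPPA"),
                                            c("HC", "nfvPPA"),
                                            c("svPPA", "nfvPPA")),
                           feature_sets = c("clinical", "clinical_radiomics"),
                           positive_class = NULL,
                           train_fraction = 0.7, cutoff = 0.9,
                           space = hp_space(), filter_clinical = TRUE,
                           seed = 1L) {
  feature_sets <- match.arg(feature_sets, several.ok = TRUE)
  clin <- intersect(clinical_score_cols(), names(features))
  rad <- attr(features, "radiomic_features")
  if (is.null(rad)) {
    rad <- setdiff(names(features)[vapply(features, is.numeric, TRUE)],
                   c("subject_id", "group", clin))
  }
  results <- list()
  summary_rows <- list()
  for (ci in seq_along(contrasts)) {
    pair <- contrasts[[ci]]
    if (!all(pair %in% features$group)) {
      rlang::abort(sprintf("Contrast %s references absent groups.",
                           paste(pair, collapse = " vs ")))
    }
    cname <- paste(pair, collapse = "_vs_")
    sub <- features[features$group %in% pair, , drop = FALSE]
    pos <- if (!is.null(positive_class) && cname %in% names(positive_class)) {
      positive_class[[cname]]
    } else {
      default_positive(pair)
    }
    split <- tryCatch(
      stratified_split(sub$group, train_fraction, seed = seed * 100L + ci),
      error = function(e) {
        rlang::abort(sprintf("[%s] split stage failed: %s", cname,
                             conditionMessage(e)))
      }
    )
    train <- sub[split$train, , drop = FALSE]
    test <- sub[split$test, , drop = FALSE]
    for (fs in feature_sets) {
      stage <- function(what, expr) {
        tryCatch(expr, error = function(e) {
          rlang::abort(sprintf("[%s / %s] %s stage failed: %s",
                               cname, fs, what, conditionMessage(e)))
        })
      }
      if (fs == "clinical") {
        filt <- NULL
        feats <- clin
      } else {
        filter_cols <- if (filter_clinical) c(clin, rad) else rad
        filt <- stage("filter", iterative_correlation_filter(
          train[, filter_cols, drop = FALSE], cutoff = cutoff, exclude = NULL
        ))
        feats <- if (filter_clinical) {
          filt$retained
        } else {
          c(clin, filt$retained)
        }
      }
      model <- stage("tune", tune_classifier(
        train, positive = pos, features = feats, space = space,
        seed = seed * 100L + ci * 10L + match(fs, feature_sets)
      ))
      metrics <- stage("evaluate", evaluate_model(model, test))
      shap <- stage("explain", shapley_attributions(
        model, train[, c("subject_id", "group", feats), drop = FALSE]
      ))
      results[[cname]][[fs]] <- list(
        filter = filt, model = model, metrics = metrics, shap = shap,
        split = split, positive_class = pos
      )
      summary_rows[[length(summary_rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(contrast = cname, feature_set = fs,
                       positive_class = pos, n_train = nrow(train),
                       n_test = nrow(test), n_features = length(feats)),
        metrics$metrics
      )
    }
  }
  structure(
    list(results = results, summary = dplyr::bind_rows(summary_rows),
         seed = seed),
    class = "ppa_experiment"
  )
}

#' @export
print.ppa_experiment <- function(x, ...) {
  cat(sprintf("<ppa_experiment> %d contrast x feature-set fits (seed %d)\n",
              nrow(x$summary), x$seed))
  print(x$summary)
  invisible(x)
}

#' Write all experiment artifacts to a directory
#'
#' JSON metric reports (Table-2/3-style fields), filter JSONs, SHAP ranked
#' tables and beeswarm figures, one subdirectory per contrast x feature set.
#'
#' @param experiment A `ppa_experiment`.
#' @param dir Output directory.
#' @param device Figure format for the beeswarms.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir, device = "png") {
  stopifnot(inherits(experiment, "ppa_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(experiment$summary, file.path(dir, "summary.csv"))
  for (cname in names(experiment$results)) {
    for (fs in names(experiment$results[[cname]])) {
      res <- experiment$results[[cname]][[fs]]
      sub <- file.path(dir, cname, fs)
      dir.create(sub, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(
        c(as.list(res$metrics$metrics),
          list(confusion = as.list(res$metrics$confusion),
               positive_class = res$positive_class,
               best_params = res$model$best_params,
               seed = experiment$seed)),
        file.path(sub, "metrics.json"), auto_unbox = TRUE, digits = NA
      )
      if (!is.null(res$filter)) {
        write_filter_json(res$filter, file.path(sub, "filter.json"))
      }
      export_beeswarm(res$shap, sub, device = device)
    }
  }
  invisible(dir)
}

#' Cohort descriptive statistics with omnibus and post-hoc tests
#'
#' A Table-1-style report: per-group mean (SD) for continuous variables and
#' count (%) for sex, a Kruskal-Wallis omnibus test for continuous
#' variables, a chi-square test for sex, and pairwise two-sample Wilcoxon
#' rank-sum post-hoc tests run only when the omnibus test is significant.
#' (Groups are independent, so the rank-sum test is the coherent pairwise
#' follow-up; a signed-rank test would require paired observations.)
#'
#' @param clinical Tibble with `group` and the clinical score columns.
#' @param variables Continuous variables to test; defaults to the clinical
#'   score columns present in `clinical`. `sex`, when present, is always
#'   treated as categorical.
#' @param posthoc_alpha Omnibus significance gate for post-hoc testing.
#' @param p_adjust Multiplicity adjustment for post-hoc p-values
#'   (`"none"` default, or any [stats::p.adjust()] method).
#' @return A `ppa_cohort_stats`: `tests` (variable, type, statistic, df,
#'   p_value, note), `group_summary`, `posthoc`.
#' @export
cohort_stats <- function(clinical, variables = NULL, posthoc_alpha = 0.05,
                         p_adjust = "none") {
  groups <- unique(clinical$group)
  if (length(groups) < 2) rlang::abort("Need at least 2 groups.")
  if (any(table(clinical$group) < 3)) {
    rlang::abort("Need at least 3 subjects per group.")
  }
  cont <- variables %||%
    setdiff(intersect(clinical_score_cols(), names(clinical)), "sex")
  tests <- list()
  posthoc <- list()
  group_summary <- list()
  for (v in cont) {
    vals <- clinical[[v]]
    group_summary[[v]] <- clinical |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(mean = mean(.data[[v]]), sd = stats::sd(.data[[v]]),
                       .groups = "drop") |>
      dplyr::mutate(variable = v, .before = 1)
    if (stats::sd(vals) == 0) {
      tests[[v]] <- tibble::tibble(
        variable = v, type = "continuous", statistic = NA_real_,
        df = NA_real_, p_value = NA_real_,
        note = "constant across all subjects; statistic undefined"
      )
      next
    }
    kw <- stats::kruskal.test(vals, factor(clinical$group))
    tests[[v]] <- tibble::tibble(
      variable = v, type = "continuous",
      statistic = unname(kw$statistic), df = unname(kw$parameter),
      p_value = kw$p.value, note = NA_character_
    )
    if (!is.na(kw$p.value) && kw$p.value < posthoc_alpha) {
      pairs <- utils::combn(sort(groups), 2, simplify = FALSE)
      pvals <- vapply(pairs, function(pr) {
        suppressWarnings(stats::wilcox.test(
          vals[clinical$group == pr[1]], vals[clinical$group == pr[2]],
          exact = FALSE
        )$p.value)
      }, 0)
      posthoc[[v]] <- tibble::tibble(
        variable = v,
        group1 = vapply(pairs, `[`, "", 1),
        group2 = vapply(pairs, `[`, "", 2),
        p_value = stats::p.adjust(pvals, method = p_adjust)
      )
    }
  }
  if ("sex" %in% names(clinical)) {
    tab <- table(clinical$group, clinical$sex)
    group_summary[["sex"]] <- clinical |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(count = sum(.data$sex == 1),
                       percent = 100 * mean(.data$sex == 1),
                       .groups = "drop") |>
      dplyr::mutate(variable = "sex", .before = 1)
    if (ncol(tab) < 2) {
      tests[["sex"]] <- tibble::tibble(
        variable = "sex", type = "categorical", statistic = NA_real_,
        df = NA_real_, p_value = NA_real_,
        note = "constant across all subjects; statistic undefined"
      )
    } else {
      cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      tests[["sex"]] <- tibble::tibble(
        variable = "sex", type = "categorical",
        statistic = unname(cs$statistic), df = unname(cs$parameter),
        p_value = cs$p.value, note = NA_character_
      )
    }
  }
  structure(
    list(
      tests = dplyr::bind_rows(tests),
      group_summary = dplyr::bind_rows(group_summary),
      posthoc = if (length(posthoc)) {
        dplyr::bind_rows(posthoc)
      } else {
        tibble::tibble(variable = character(), group1 = character(),
                       group2 = character(), p_value = double())
      },
      posthoc_alpha = posthoc_alpha, p_adjust = p_adjust
    ),
    class = "ppa_cohort_stats"
  )
}

#' @export
print.ppa_cohort_stats <- function(x, ...) {
  cat("<ppa_cohort_stats>\n")
  print(x$tests)
  invisible(x)
}
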