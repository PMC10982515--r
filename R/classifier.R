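#' Stratified train/test split
#'
#' Splits sample indices per class: each class contributes
#' `floor(train_fraction * n_class)` samples to the training set and the
#' rest to the test set, so a 53/31/25 cohort at 0.70 trains on 37/21/17
#' and tests on 16/10/8.
#'
#' @param labels Vector of class labels (one per sample).
#' @param train_fraction Proportion of each class used for training.
#' @param seed Integer seed for the per-class sampling.
#' @return List with sorted integer vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    rlang::abort("`train_fraction` must be in (0, 1).")
  }
  set.seed(seed)
  train <- integer()
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 2) {
      rlang::abort(sprintf("Class '%s' has fewer than 2 samples.", cl))
    }
    n_train <- floor(train_fraction * length(idx))
    if (n_train == 0 || n_train == length(idx)) {
      rlang::abort(sprintf(
        "Class '%s' would have an empty train or test set.", cl
      ))
    }
    train <- c(train, sample(idx, n_train))
  }
  list(train = sort(train), test = sort(setdiff(seq_along(labels), train)))
}

#' Hyperparameter search space for the boosted-tree classifier
#'
#' The randomized-search ranges: learning rate uniform on
#' \[0.01, 0.1\], maximum depth uniform on the integers \[3, 10\], number of
#' boosting rounds on \[50, 200\], row subsampling on \[0.5, 1\]; 60
#' candidates scored by mean AUC-ROC over stratified 5-fold CV. L1/L2
#' regularization strengths are not tuned and stay at the ensemble defaults
#' (`alpha = 0`, `lambda = 1`), recorded in the fitted model's parameters.
#'
#' @param learning_rate,max_depth,n_estimators,subsample Length-2 ranges.
#' @param n_iterations Number of sampled candidates.
#' @param cv_folds Number of stratified CV folds.
#' @return A `hyperparameter_space` list.
#' @export
hp_space <- function(learning_rate = c(0.01, 0.1), max_depth = c(3L, 10L),
                     n_estimators = c(50L, 200L), subsample = c(0.5, 1),
                     n_iterations = 60L, cv_folds = 5L) {
  stopifnot(
    learning_rate[1] <= learning_rate[2], max_depth[1] <= max_depth[2],
    n_estimators[1] <= n_estimators[2], subsample[1] <= subsample[2],
    n_iterations >= 1, cv_folds >= 2
  )
  structure(
    list(learning_rate = learning_rate, max_depth = as.integer(max_depth),
         n_estimators = as.integer(n_estimators), subsample = subsample,
         n_iterations = as.integer(n_iterations),
         cv_folds = as.integer(cv_folds)),
    class = "hyperparameter_space"
  )
}

# Mann-Whitney AUC (ties handled by midranks); NA if one class is absent.
auc_mw <- function(y, score) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified k-fold assignment; errors if a class cannot reach every fold.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < k) {
      rlang::abort(sprintf(
        "Class '%s' has %d samples, fewer than %d folds: a fold would hold a single class.",
        cl, length(idx), k
      ))
    }
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

feature_matrix <- function(data, features) {
  missing <- setdiff(features, names(data))
  if (length(missing)) {
    rlang::abort(sprintf(
      "Feature columns missing from data: %s%s",
      paste(utils::head(missing, 5), collapse = ", "),
      if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5) else ""
    ))
  }
  as.matrix(data[, features, drop = FALSE])
}

xgb_fit <- function(x, y, params, nrounds, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(
    params = c(params, list(
      objective = "binary:logistic", nthread = 1, seed = seed,
      lambda = 1, alpha = 0,
      # exact greedy splits: thresholds at midpoints between adjacent
      # values, not at histogram bin edges — at these sample sizes the
      # quantile sketch is pointless and edge-hugging splits misroute new
      # extremes of a class
      tree_method = "exact"
    )),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
}

#' Tune a gradient-boosted tree classifier by randomized search
#'
#' Samples `n_iterations` candidates uniformly from the hyperparameter
#' space, scores each by mean AUC-ROC over stratified `cv_folds`-fold
#' cross-validation on the training table, and refits the best candidate on
#' the whole training split. Deterministic for a fixed `seed`. The positive
#' class is the patient group of the contrast (configurable).
#'
#' @param data Training tibble: label column plus numeric feature columns.
#' @param positive Label treated as the positive class.
#' @param features Feature column names; default: every numeric column
#'   except `subject_id`/`group`.
#' @param label_col Name of the label column.
#' @param space A [hp_space()].
#' @param seed Integer seed for candidate sampling, fold assignment and the
#'   ensemble's row subsampling.
#' @return A `ppa_model`: the fitted booster, `best_params`, the per-
#'   candidate `cv_results` tibble, the feature list and class labels.
#' @export
tune_classifier <- function(data, positive, features = NULL,
                            label_col = "group", space = hp_space(),
                            seed = 1L) {
  labels <- data[[label_col]]
  classes <- unique(labels)
  if (length(classes) != 2) rlang::abort("Binary labels required.")
  if (!positive %in% classes) {
    rlang::abort(sprintf("Positive class '%s' not found in labels.", positive))
  }
  if (is.null(features)) {
    features <- setdiff(names(data)[vapply(data, is.numeric, TRUE)],
                        c("subject_id", label_col))
  }
  y <- as.integer(labels == positive)
  x <- feature_matrix(data, features)
  set.seed(seed)
  runif_int <- function(n, lo, hi) {  # uniform on {lo, ..., hi}
    lo + floor(stats::runif(n) * (hi - lo + 1L))
  }
  cand <- tibble::tibble(
    candidate = seq_len(space$n_iterations),
    learning_rate = stats::runif(space$n_iterations, space$learning_rate[1],
                                 space$learning_rate[2]),
    max_depth = as.integer(runif_int(space$n_iterations, space$max_depth[1],
                                     space$max_depth[2])),
    n_estimators = as.integer(runif_int(space$n_iterations,
                                        space$n_estimators[1],
                                        space$n_estimators[2])),
    subsample = stats::runif(space$n_iterations, space$subsample[1],
                             space$subsample[2])
  )
  fold <- stratified_folds(y, space$cv_folds)
  xgb_seed <- sample.int(2^30, 1)
  cv_auc <- vapply(seq_len(space$n_iterations), function(ci) {
    aucs <- vapply(seq_len(space$cv_folds), function(k) {
      tr <- fold != k
      fit <- xgb_fit(
        x[tr, , drop = FALSE], y[tr],
        params = list(eta = cand$learning_rate[ci],
                      max_depth = cand$max_depth[ci],
                      subsample = cand$subsample[ci]),
        nrounds = cand$n_estimators[ci],
        seed = xgb_seed + ci * space$cv_folds + k
      )
      auc_mw(y[!tr], predict(fit, xgboost::xgb.DMatrix(
        x[!tr, , drop = FALSE], nthread = 1)))
    }, 0)
    mean(aucs)
  }, 0)
  cand$mean_cv_auc <- cv_auc
  best <- which.max(cv_auc)
  booster <- xgb_fit(
    x, y,
    params = list(eta = cand$learning_rate[best],
                  max_depth = cand$max_depth[best],
                  subsample = cand$subsample[best]),
    nrounds = cand$n_estimators[best],
    seed = xgb_seed
  )
  structure(
    list(
      booster = booster,
      best_params = c(as.list(cand[best, c("learning_rate", "max_depth",
                                           "n_estimators", "subsample")]),
                      list(lambda = 1, alpha = 0)),
      cv_results = cand,
      features = features,
      positive_class = positive,
      negative_class = setdiff(classes, positive),
      label_col = label_col
    ),
    class = "ppa_model"
  )
}

#' @export
print.ppa_model <- function(x, ...) {
  bp <- x$best_params
  cat(sprintf(
    "<ppa_model> positive = %s, %d features\n  best: eta %.3f, depth %d, rounds %d, subsample %.2f (CV AUC %.3f)\n",
    x$positive_class, length(x$features), bp$learning_rate, bp$max_depth,
    bp$n_estimators, bp$subsample,
    max(x$cv_results$mean_cv_auc)
  ))
  invisible(x)
}

#' Predict class probabilities from a tuned model
#'
#' @param object A `ppa_model`.
#' @param newdata Tibble containing the model's feature columns.
#' @param type `"prob"` for positive-class probabilities, `"margin"` for
#'   raw log-odds, `"contrib"` for per-feature Shapley contributions.
#' @param ... Unused.
#' @return Numeric vector, or a matrix for `type = "contrib"`.
#' @export
predict.ppa_model <- function(object, newdata, type = c("prob", "margin",
                                                        "contrib"), ...) {
  type <- match.arg(type)
  dm <- xgboost::xgb.DMatrix(feature_matrix(newdata, object$features),
                             nthread = 1)
  switch(type,
    prob = predict(object$booster, dm),
    margin = predict(object$booster, dm, outputmargin = TRUE),
    contrib = predict(object$booster, dm, predcontrib = TRUE)
  )
}

#' Classification metrics from confusion counts
#'
#' Standard definitions: sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' balanced accuracy (sens + spec)/2, precision TP/(TP+FP),
#' F1 = 2PR/(P+R).
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @return One-row tibble of the five threshold metrics.
#' @export
#' @examples
#' metrics_from_confusion(tp = 8, fp = 2, tn = 14, fn = 0)
metrics_from_confusion <- function(tp, fp, tn, fn) {
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else {
    NA_real_
  }
  tibble::tibble(
    sensitivity = sens, specificity = spec,
    balanced_accuracy = (sens + spec) / 2, precision = prec, f1 = f1
  )
}

#' Evaluate a tuned model on held-out data
#'
#' Thresholds predicted probabilities at 0.5 for the confusion matrix and
#' reports the six test-set metrics: sensitivity, specificity, balanced
#' accuracy, precision, F1 and AUC-ROC (from the probabilities; `NA` with a
#' warning if the test set has a single class).
#'
#' @param model A `ppa_model`.
#' @param data Test tibble with the label column and model features.
#' @param threshold Probability cut for the confusion matrix.
#' @return A `ppa_metrics`: one-row `metrics` tibble plus confusion counts.
#' @export
evaluate_model <- function(model, data, threshold = 0.5) {
  y <- as.integer(data[[model$label_col]] == model$positive_class)
  prob <- predict(model, data, type = "prob")
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  metrics <- metrics_from_confusion(tp, fp, tn, fn)
  auc <- auc_mw(y, prob)
  if (is.na(auc)) rlang::warn("Single-class test set: AUC-ROC undefined.")
  metrics$auc_roc <- auc
  structure(
    list(metrics = metrics,
         confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
         positive_class = model$positive_class, threshold = threshold),
    class = "ppa_metrics"
  )
}

#' @export
print.ppa_metrics <- function(x, ...) {
  cat(sprintf("<ppa_metrics> positive = %s (threshold %.2f)\n",
              x$positive_class, x$threshold))
  print(x$metrics)
  invisible(x)
}
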