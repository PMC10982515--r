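test_that("the stratified 70:30 split reproduces the study's counts", {
  labels <- rep(c("HC", "svPPA", "nfvPPA"), c(53, 31, 25))
  sp <- stratified_split(labels, 0.7, seed = 1)
  expect_equal(as.integer(table(labels[sp$train])[c("HC", "svPPA", "nfvPPA")]),
               c(37L, 21L, 17L))
  expect_equal(as.integer(table(labels[sp$test])[c("HC", "svPPA", "nfvPPA")]),
               c(16L, 10L, 8L))
  expect_equal(sort(c(sp$train, sp$test)), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_identical(sp, stratified_split(labels, 0.7, seed = 1))
  expect_false(identical(sp$train,
                         stratified_split(labels, 0.7, seed = 2)$train))
})

test_that("degenerate splits are rejected", {
  expect_error(stratified_split(c("a", "a", "b"), 0.7), "fewer than 2")
  expect_error(stratified_split(rep(c("a", "b"), c(10, 2)), 0.4),
               "empty train or test")
  expect_error(stratified_split(rep("a", 10), 0), "train_fraction")
})

test_that("metric identities hold on hand-computed confusions", {
  m <- metrics_from_confusion(tp = 9, fn = 1, tn = 8, fp = 2)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$balanced_accuracy, 0.85)
  expect_equal(m$precision, 9 / 11)
  expect_equal(m$f1, 2 * (9 / 11) * 0.9 / ((9 / 11) + 0.9))
  # the published patient-vs-patient test pairing: sens 1, spec 0.875
  t3 <- metrics_from_confusion(tp = 8, fn = 0, tn = 14, fp = 2)
  expect_equal(t3$sensitivity, 1)
  expect_equal(t3$specificity, 0.875)
  expect_equal(t3$balanced_accuracy, 0.9375)
  expect_equal(round(t3$balanced_accuracy, 3), 0.938)  # prints as 0.937/0.938
  perfect <- metrics_from_confusion(tp = 5, fn = 0, tn = 7, fp = 0)
  expect_true(all(unlist(perfect) == 1))
})

test_that("randomized search samples inside the space and is deterministic", {
  d <- separable_table(seed = 3)
  sp <- hp_space(n_iterations = 8, cv_folds = 3)
  m1 <- tune_classifier(d, positive = "B", space = sp, seed = 11)
  m2 <- tune_classifier(d, positive = "B", space = sp, seed = 11)
  expect_identical(m1$best_params, m2$best_params)
  expect_identical(m1$cv_results, m2$cv_results)
  cv <- tidy(m1)
  expect_true(all(cv$learning_rate >= 0.01 & cv$learning_rate <= 0.1))
  expect_true(all(cv$max_depth %in% 3:10))
  expect_true(all(cv$n_estimators >= 50 & cv$n_estimators <= 200))
  expect_true(all(cv$subsample >= 0.5 & cv$subsample <= 1))
  expect_equal(nrow(cv), 8L)
  g <- glance(m1)
  expect_equal(g$lambda, 1)
  expect_equal(g$alpha, 0)
})

test_that("a collapsed space returns its single point", {
  d <- separable_table(seed = 4)
  sp <- hp_space(learning_rate = c(0.05, 0.05), max_depth = c(4, 4),
                 n_estimators = c(60, 60), subsample = c(1, 1),
                 n_iterations = 3, cv_folds = 2)
  m <- tune_classifier(d, positive = "B", space = sp, seed = 1)
  expect_equal(m$best_params$learning_rate, 0.05)
  expect_equal(m$best_params$max_depth, 4L)
  expect_equal(m$best_params$n_estimators, 60L)
  expect_equal(m$best_params$subsample, 1)
})

test_that("stratification errors when a class cannot reach every fold", {
  d <- separable_table(n_a = 12, n_b = 3, seed = 5)
  expect_error(
    tune_classifier(d, positive = "B",
                    space = hp_space(n_iterations = 2, cv_folds = 5),
                    seed = 1),
    "single class"
  )
})

test_that("evaluation reports the six metrics with the BA identity", {
  d <- separable_table(seed = 6)
  sp <- stratified_split(d$group, 0.7, seed = 2)
  m <- tune_classifier(d[sp$train, ], positive = "B",
                       space = hp_space(n_iterations = 4, cv_folds = 3),
                       seed = 2)
  ev <- evaluate_model(m, d[sp$test, ])
  expect_s3_class(ev, "ppa_metrics")
  expect_equal(ev$metrics$balanced_accuracy,
               (ev$metrics$sensitivity + ev$metrics$specificity) / 2)
  expect_true(all(unlist(ev$metrics) >= 0 & unlist(ev$metrics) <= 1))
  expect_equal(sum(ev$confusion), length(sp$test))
  # separable classes are classified perfectly
  expect_equal(ev$metrics$balanced_accuracy, 1)
  # single-class test set: AUC undefined
  expect_warning(ev1 <- evaluate_model(m, d[d$group == "B", ][1:5, ]),
                 "AUC")
  expect_true(is.na(ev1$metrics$auc_roc))
})

test_that("the rank AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  y <- rbinom(60, 1, 0.4)
  s <- rnorm(60) + y
  ours <- ppaRadiomics:::auc_mw(y, s)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("separable data yields near-perfect test accuracy across seeds", {
  sp <- hp_space(n_iterations = 6, cv_folds = 3)
  ba <- vapply(1:20, function(s) {
    d <- separable_table(n_a = 40, n_b = 32, seed = 100 + s)
    idx <- stratified_split(d$group, 0.7, seed = s)
    m <- tune_classifier(d[idx$train, ], positive = "B", space = sp,
                         seed = s)
    evaluate_model(m, d[idx$test, ])$metrics$balanced_accuracy
  }, 0)
  expect_gte(mean(ba >= 0.95), 0.9)
})

test_that("permuting training labels drives test accuracy to chance", {
  sp <- hp_space(n_iterations = 4, cv_folds = 3)
  ba <- vapply(1:6, function(s) {
    d <- separable_table(n_a = 40, n_b = 32, seed = 200 + s)
    idx <- stratified_split(d$group, 0.7, seed = s)
    train <- d[idx$train, ]
    set.seed(s)
    train$group <- sample(train$group)
    m <- tune_classifier(train, positive = "B", space = sp, seed = s)
    evaluate_model(m, d[idx$test, ])$metrics$balanced_accuracy
  }, 0)
  expect_lt(abs(mean(ba) - 0.5), 0.2)
})
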