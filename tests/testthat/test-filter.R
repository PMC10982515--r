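test_that("the worked three-feature example removes A and keeps {B, C}", {
  r <- diag(3)
  colnames(r) <- rownames(r) <- c("A", "B", "C")
  # |r|(B,C) must exceed 0.205 for the matrix to be positive definite;
  # 0.25 keeps every decision of the worked procedure intact
  r["A", "B"] <- r["B", "A"] <- 0.95
  r["A", "C"] <- r["C", "A"] <- 0.50
  r["B", "C"] <- r["C", "B"] <- 0.25
  d <- exact_corr_data(r, n = 24, seed = 2)
  expect_equal(abs(cor(d)), abs(r), tolerance = 1e-10, ignore_attr = TRUE)
  res <- iterative_correlation_filter(d, cutoff = 0.9, exclude = NULL)
  expect_equal(res$retained, c("B", "C"))
  expect_equal(res$removed$feature, "A")
  expect_equal(res$removed$partner, "B")
  expect_equal(res$removed$pair_abs_r, 0.95, tolerance = 1e-10)
  expect_equal(res$removed$mean_abs_r, 0.725, tolerance = 1e-10)
})

test_that("no pair above the cutoff leaves the table untouched", {
  set.seed(4)
  d <- tibble::as_tibble(matrix(rnorm(200), 20, 10,
                                dimnames = list(NULL, paste0("f", 1:10))))
  res <- iterative_correlation_filter(d, cutoff = 0.99, exclude = NULL)
  expect_equal(res$retained, paste0("f", 1:10))
  expect_equal(nrow(res$removed), 0L)
})

test_that("a duplicated column (|r| = 1) loses exactly one of the pair", {
  set.seed(5)
  d <- tibble::tibble(a = rnorm(30), c = rnorm(30))
  d$b <- d$a
  d <- d[, c("a", "b", "c")]
  res <- iterative_correlation_filter(d, exclude = NULL)
  expect_equal(sort(res$removed$feature), "b")  # later column by tie rule
  expect_true("a" %in% res$retained)
})

test_that("output max |r| < cutoff and the filter is idempotent", {
  set.seed(6)
  n <- 40
  base <- matrix(rnorm(n * 6), n, 6)
  # correlated companions
  x <- cbind(base, base[, 1:4] + matrix(rnorm(n * 4, sd = 0.1), n, 4))
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  d <- tibble::as_tibble(x)
  res <- iterative_correlation_filter(d, cutoff = 0.9, exclude = NULL)
  cm <- abs(cor(d[res$retained]))
  diag(cm) <- 0
  expect_lt(max(cm), 0.9)
  res2 <- iterative_correlation_filter(d[res$retained], cutoff = 0.9,
                                       exclude = NULL)
  expect_equal(res2$retained, res$retained)
  expect_equal(nrow(res2$removed), 0L)
})

test_that("subject row order never changes the result", {
  set.seed(7)
  n <- 30
  x <- matrix(rnorm(n * 8), n, 8)
  x <- cbind(x, x[, 1] * 0.98 + rnorm(n, sd = 0.05))
  colnames(x) <- paste0("f", 1:9)
  d <- tibble::as_tibble(x)
  res1 <- iterative_correlation_filter(d, exclude = NULL)
  res2 <- iterative_correlation_filter(d[sample(n), ], exclude = NULL)
  expect_equal(res1$retained, res2$retained)
})

test_that("zero-variance features are dropped up front with a warning", {
  set.seed(8)
  d <- tibble::tibble(a = rnorm(20), b = rep(3, 20), c = rnorm(20))
  expect_warning(res <- iterative_correlation_filter(d, exclude = NULL),
                 "zero-variance")
  expect_equal(res$zero_variance, "b")
  expect_false("b" %in% res$retained)
})

test_that("a fitted filter applies to held-out data and serializes", {
  set.seed(9)
  d <- tibble::tibble(subject_id = sprintf("S%02d", 1:20),
                      group = rep(c("x", "y"), 10),
                      a = rnorm(20), c = rnorm(20))
  d$b <- d$a + rnorm(20, sd = 0.01)
  res <- iterative_correlation_filter(d)
  expect_equal(nrow(res$removed), 1L)
  expect_true(res$removed$feature %in% c("a", "b"))
  test_rows <- apply_filter(d[1:5, ], res)
  expect_false(res$removed$feature %in% names(test_rows))
  expect_true(all(c("subject_id", "group", res$retained) %in%
                    names(test_rows)))
  path <- withr::local_tempfile(fileext = ".json")
  write_filter_json(res, path)
  js <- jsonlite::read_json(path)
  expect_equal(unlist(js$retained), res$retained)
  expect_equal(js$cutoff, 0.9)
})

test_that("invalid inputs are rejected", {
  d <- tibble::tibble(a = rnorm(10), b = rnorm(10))
  expect_error(iterative_correlation_filter(d, cutoff = 0), "cutoff")
  expect_error(iterative_correlation_filter(d, cutoff = 1.2), "cutoff")
  expect_error(iterative_correlation_filter(d[, 1, drop = FALSE],
                                            exclude = NULL), "2 feature")
  d$a[1] <- NA
  expect_error(iterative_correlation_filter(d, exclude = NULL), "missing")
})
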