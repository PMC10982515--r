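test_that("cohort generation is deterministic and honors group sizes", {
  cfg <- tiny_config(seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$volumes[[1]]$data, b$volumes[[1]]$data)
  expect_identical(a$volumes[[22]]$data, b$volumes[[22]]$data)
  expect_equal(as.integer(table(a$clinical$group)[c("HC", "svPPA", "nfvPPA")]),
               c(8L, 7L, 7L))
  c2 <- generate_cohort(tiny_config(seed = 100))
  expect_false(identical(a$volumes[[1]]$data, c2$volumes[[1]]$data))
})

test_that("the default configuration reproduces the study design", {
  cfg <- cohort_config()
  expect_equal(unname(cfg$group_sizes), c(53, 31, 25))
  mask <- build_block_mask(cfg$regions, cfg$block_dim)
  expect_equal(nrow(mask$lookup), 68L)
  expect_equal(sort(unique(mask$lookup$hemisphere)), c("lh", "rh"))
  expect_equal(length(unique(mask$lookup$region)), 34L)
  # every ROI occupies at least 27 voxels
  counts <- table(mask$labels[mask$labels > 0])
  expect_true(all(counts >= 27))
  expect_equal(length(counts), 68L)
})

test_that("clinical scores track the configured moments and bounds", {
  cfg <- cohort_config(seed = 21)  # full 53/31/25 cohort
  clin <- withr::with_seed(21, generate_clinical(cfg))
  hc <- clin[clin$group == "HC", ]
  sv <- clin[clin$group == "svPPA", ]
  nf <- clin[clin$group == "nfvPPA", ]
  # sample mean within 3 SE of the configured mean
  expect_lt(abs(mean(hc$bnt) - 14.32), 3 * 0.89 / sqrt(53))
  expect_lt(abs(mean(sv$fluency_animal) - 9.03), 3 * 4.15 / sqrt(31))
  # group ordering of the naming score
  expect_lt(mean(sv$bnt), mean(nf$bnt))
  # truncation bounds from the test definitions
  expect_true(all(clin$bnt >= 0 & clin$bnt <= 15))
  expect_true(all(clin$cdr >= 0))
  expect_true(all(clin$fluency_animal >= 0 & clin$fluency_dwords >= 0))
  expect_true(all(clin$sex %in% 0:1))
  # SD = 0 is degenerate: every HC CDR-language equals the mean
  expect_true(all(hc$cdr_language == 0))
})

test_that("zero effect leaves ROI intensities exchangeable across groups", {
  cfg <- cohort_config(
    group_sizes = c(HC = 30, svPPA = 30),
    regions = c("entorhinal", "cuneus"),
    effect_spec = effect_spec_default()[0, ],
    seed = 5
  )
  cohort <- generate_cohort(cfg)
  roi_mean <- vapply(cohort$volumes, function(v) {
    mean(v$data[cohort$mask$labels == 1L])
  }, 0)
  ks <- ks.test(roi_mean[cohort$clinical$group == "HC"],
                roi_mean[cohort$clinical$group == "svPPA"])
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted effect shifts that ROI's features between groups", {
  cfg <- cohort_config(
    group_sizes = c(HC = 50, svPPA = 50),
    regions = c("entorhinal", "cuneus"),
    effect_spec = tibble::tibble(group = "svPPA", roi = "lh_entorhinal",
                                 mean_shift = -15, texture_shift = 3),
    seed = 6
  )
  cohort <- generate_cohort(cfg)
  grp <- cohort$clinical$group
  lab_eff <- cohort$mask$lookup$label_id[
    cohort$mask$lookup$roi == "lh_entorhinal"]
  lab_ctl <- cohort$mask$lookup$label_id[
    cohort$mask$lookup$roi == "lh_cuneus"]
  m_eff <- vapply(cohort$volumes,
                  function(v) mean(v$data[cohort$mask$labels == lab_eff]), 0)
  m_ctl <- vapply(cohort$volumes,
                  function(v) mean(v$data[cohort$mask$labels == lab_ctl]), 0)
  w_eff <- wilcox.test(m_eff[grp == "HC"], m_eff[grp == "svPPA"])
  w_ctl <- wilcox.test(m_ctl[grp == "HC"], m_ctl[grp == "svPPA"])
  expect_lt(w_eff$p.value, 0.01)
  expect_gt(w_ctl$p.value, 0.01)
})

test_that("configuration errors are caught", {
  expect_error(cohort_config(effect_spec = tibble::tibble(
    group = "svPPA", roi = "lh_nowhere", mean_shift = -1, texture_shift = 1
  )), "not in the layout")
  bad_moments <- clinical_moments_default()
  bad_moments$sd[1] <- -1
  expect_error(cohort_config(clinical_moments = bad_moments), "SDs")
  expect_error(cohort_config(group_sizes = c(5, 5)), "named")
  expect_error(cohort_config(group_sizes = c(HC = -1, svPPA = 5)), ">= 0")
  expect_error(cohort_config(block_dim = c(2, 2, 2)), "27")
})

test_that("a cohort round-trips through NIfTI and CSV", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(group_sizes = c(HC = 2, svPPA = 2),
                       regions = "entorhinal", block_dim = c(3, 3, 3),
                       effect_spec = effect_spec_default()[1, ], seed = 3)
  cohort <- generate_cohort(cfg)
  write_cohort(cohort, dir)
  # exact clinical header contract
  header <- readLines(file.path(dir, "clinical.csv"), n = 1)
  expect_equal(header, paste("subject_id,group,age,sex,education,cdr",
                             "cdr_language,fluency_animal,fluency_dwords,bnt",
                             sep = ","))
  vol <- read_volume_nifti(file.path(dir, "S001.nii.gz"))
  expect_equal(vol$data, cohort$volumes[["S001"]]$data, tolerance = 1e-6)
  mask <- read_mask_nifti(file.path(dir, "mask.nii.gz"),
                          file.path(dir, "labels.csv"))
  expect_identical(mask$labels, cohort$mask$labels)
  expect_equal(mask$lookup, cohort$mask$lookup)
})
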