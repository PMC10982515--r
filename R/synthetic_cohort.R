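#' Desikan-Killiany cortical region names
#'
#' The 34 region names of the Desikan-Killiany atlas. Crossed with the two
#' hemispheres they name the 68 white-matter ROIs of a wmparc-style
#' parcellation (`lh_entorhinal`, `rh_entorhinal`, ...).
#'
#' @return Character vector of 34 region names.
#' @export
dk_regions <- function() {
  c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal"
  )
}

#' Published group moments for the clinical and cognitive scores
#'
#' Per-group mean and SD of the demographic and clinical variables of the
#' PPA study cohort (healthy controls, semantic variant, non-fluent variant),
#' together with the truncation bounds implied by each test's definition
#' (e.g. Boston Naming Test scored 0-15, CDR non-negative).
#'
#' @return Tibble with columns `group`, `score`, `mean`, `sd`, `lower`,
#'   `upper`.
#' @export
clinical_moments_default <- function() {
  tibble::tribble(
    ~group,    ~score,            ~mean, ~sd,   ~lower, ~upper,
    "HC",      "age",             64.11, 6.33,  18,     100,
    "nfvPPA",  "age",             66.56, 6.66,  18,     100,
    "svPPA",   "age",             62.97, 6.43,  18,     100,
    "HC",      "education",       21.96, 19.13, 0,      30,
    "nfvPPA",  "education",       15.80, 2.60,  0,      30,
    "svPPA",   "education",       19.06, 15.08, 0,      30,
    "HC",      "cdr",             0.03,  0.12,  0,      3,
    "nfvPPA",  "cdr",             0.44,  0.34,  0,      3,
    "svPPA",   "cdr",             0.65,  0.32,  0,      3,
    "HC",      "cdr_language",    0.00,  0.00,  0,      3,
    "nfvPPA",  "cdr_language",    1.25,  0.77,  0,      3,
    "svPPA",   "cdr_language",    0.95,  0.51,  0,      3,
    "HC",      "fluency_animal",  23.53, 5.14,  0,      Inf,
    "nfvPPA",  "fluency_animal",  11.88, 8.69,  0,      Inf,
    "svPPA",   "fluency_animal",  9.03,  4.15,  0,      Inf,
    "HC",      "fluency_dwords",  15.87, 4.13,  0,      Inf,
    "nfvPPA",  "fluency_dwords",  6.60,  6.18,  0,      Inf,
    "svPPA",   "fluency_dwords",  8.97,  4.48,  0,      Inf,
    "HC",      "bnt",             14.32, 0.89,  0,      15,
    "nfvPPA",  "bnt",             12.52, 2.45,  0,      15,
    "svPPA",   "bnt",             5.71,  3.53,  0,      15
  )
}

#' Default planted group effects
#'
#' By default the generator plants effects that mirror the study's main
#' imaging findings: white matter near the left entorhinal cortex altered in
#' the semantic variant, left caudal middle frontal white matter in the
#' non-fluent variant. Patients get *lower* intensities (atrophy-like mean
#' shift) and spatially smoother texture (longer noise correlation length).
#'
#' @return Tibble with columns `group`, `roi`, `mean_shift`,
#'   `texture_shift` (multiplier on the noise correlation length).
#' @export
effect_spec_default <- function() {
  tibble::tribble(
    ~group,   ~roi,                      ~mean_shift, ~texture_shift,
    "svPPA",  "lh_entorhinal",           -15,         3,
    "nfvPPA", "lh_caudalmiddlefrontal",  -15,         3
  )
}

#' Configuration for the synthetic PPA cohort generator
#'
#' Bundles everything the generator needs: group sizes (defaults are the
#' study's 53 HC / 31 svPPA / 25 nfvPPA), the ROI layout (regions x
#' hemispheres tiled as rectangular blocks), the planted group effects,
#' the clinical score moments, sex proportions, and the intensity model
#' (baseline mean, white-noise SD, base correlation length in voxels).
#'
#' @param group_sizes Named integer vector of subjects per group.
#' @param regions Character vector of region names (one block per region and
#'   hemisphere).
#' @param block_dim Integer length-3; voxels per ROI block (>= 27 voxels
#'   total so texture matrices are non-degenerate).
#' @param effect_spec Tibble `group, roi, mean_shift, texture_shift`; see
#'   [effect_spec_default()].
#' @param clinical_moments Tibble as [clinical_moments_default()].
#' @param sex_female_prop Named vector, probability a subject is female.
#' @param baseline_mean,noise_sd Intensity model: ROI voxels are
#'   `baseline_mean + mean_shift + noise_sd * field` with a unit-variance
#'   noise field.
#' @param base_corr_length Correlation length (voxels) of the unaffected
#'   noise field; `texture_shift` multiplies it. Below 0.5 voxels the field
#'   is white noise.
#' @param seed Integer seed; mandatory, drives all randomness.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(group_sizes = c(HC = 53, svPPA = 31, nfvPPA = 25),
                          regions = dk_regions(),
                          block_dim = c(6, 6, 6),
                          effect_spec = effect_spec_default(),
                          clinical_moments = clinical_moments_default(),
                          sex_female_prop = c(HC = 30 / 53, svPPA = 15 / 31,
                                              nfvPPA = 14 / 25),
                          baseline_mean = 100,
                          noise_sd = 10,
                          base_corr_length = 0.4,
                          seed = 1L) {
  if (is.null(names(group_sizes)) || any(names(group_sizes) == "")) {
    rlang::abort("`group_sizes` must be named by group.")
  }
  if (any(group_sizes < 0)) rlang::abort("Group sizes must be >= 0.")
  if (prod(block_dim) < 27) {
    rlang::abort("ROI blocks must contain at least 27 voxels.")
  }
  rois <- as.vector(outer(c("lh", "rh"), regions, paste, sep = "_"))
  effect_spec <- tibble::as_tibble(effect_spec)
  if (nrow(effect_spec)) {
    bad <- setdiff(effect_spec$roi, rois)
    if (length(bad)) {
      rlang::abort(sprintf(
        "Effect ROIs not in the layout: %s", paste(bad, collapse = ", ")
      ))
    }
  }
  clinical_moments <- tibble::as_tibble(clinical_moments)
  if (any(clinical_moments$sd < 0)) {
    rlang::abort("Clinical SDs must be >= 0.")
  }
  structure(
    list(
      group_sizes = group_sizes, regions = regions, block_dim = block_dim,
      effect_spec = effect_spec, clinical_moments = clinical_moments,
      sex_female_prop = sex_female_prop, baseline_mean = baseline_mean,
      noise_sd = noise_sd, base_corr_length = base_corr_length,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Grid of blocks covering n ROIs: near-cubic block counts per axis.
block_grid <- function(n_roi) {
  nx <- ceiling(n_roi^(1 / 3))
  ny <- ceiling(sqrt(n_roi / nx))
  nz <- ceiling(n_roi / (nx * ny))
  c(nx, ny, nz)
}

#' Deterministic block parcellation for a synthetic cohort
#'
#' Tiles a 3D grid into one rectangular block per ROI (regions x {lh, rh}).
#' Texture statistics are location-agnostic, so blocks stand in for anatomy
#' while keeping extraction exact. Labels 1..n follow lh then rh region
#' order; unused trailing blocks are background (0).
#'
#' @param regions Region names (one block per region and hemisphere).
#' @param block_dim Voxels per block along each axis.
#' @return A [parcellation_mask()].
#' @export
build_block_mask <- function(regions = dk_regions(), block_dim = c(6, 6, 6)) {
  hemi <- c("lh", "rh")
  lookup <- tibble::tibble(
    label_id = seq_len(2L * length(regions)),
    hemisphere = rep(hemi, each = length(regions)),
    region = rep(regions, times = 2L)
  )
  n_roi <- nrow(lookup)
  grid <- block_grid(n_roi)
  shape <- grid * block_dim
  labels <- array(0L, dim = shape)
  block_of <- expand.grid(
    x = seq_len(grid[1]), y = seq_len(grid[2]), z = seq_len(grid[3])
  )
  for (b in seq_len(n_roi)) {
    bx <- (block_of$x[b] - 1L) * block_dim[1]
    by <- (block_of$y[b] - 1L) * block_dim[2]
    bz <- (block_of$z[b] - 1L) * block_dim[3]
    labels[
      bx + seq_len(block_dim[1]), by + seq_len(block_dim[2]),
      bz + seq_len(block_dim[3])
    ] <- b
  }
  parcellation_mask(labels, lookup)
}

# Truncated-normal sampler whose *truncated* mean equals `mean`: the
# underlying location is solved by uniroot, scale stays at `sd`. With heavy
# truncation the realized SD falls below `sd`; the mean contract is what the
# cohort statistics rely on.
rtrunc_norm_meanmatched <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  if (mean < lower || mean > upper) {
    rlang::abort("Configured mean lies outside the truncation bounds.")
  }
  trunc_mean <- function(mu) {
    a <- (lower - mu) / sd
    b <- (upper - mu) / sd
    mass <- stats::pnorm(a, lower.tail = FALSE) -
      stats::pnorm(b, lower.tail = FALSE)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / mass
  }
  f <- function(mu) trunc_mean(mu) - mean
  lo <- mean - 8 * sd
  hi <- mean + 8 * sd
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || flo > 0) lo <- mean - 30 * sd
  if (!is.finite(fhi) || fhi < 0) hi <- mean + 30 * sd
  mu0 <- tryCatch(
    stats::uniroot(f, c(lo, hi), tol = 1e-10)$root,
    error = function(e) mean
  )
  a <- (lower - mu0) / sd
  b <- (upper - mu0) / sd
  u <- stats::runif(n, stats::pnorm(a), stats::pnorm(b))
  pmin(pmax(mu0 + sd * stats::qnorm(u), lower), upper)
}

#' Draw the clinical and cognitive table for a synthetic cohort
#'
#' Scores are drawn per group from truncated normal distributions matching
#' the configured group means at the configured scale, truncated at each
#' test's plausible bounds; sex is Bernoulli with the configured female
#' proportion. Uses the current RNG state ([generate_cohort()] seeds it).
#'
#' @param config A [cohort_config()].
#' @return Tibble with columns `subject_id`, `group`, `age`, `sex`
#'   (1 = female), `education`, `cdr`, `cdr_language`, `fluency_animal`,
#'   `fluency_dwords`, `bnt`.
#' @export
generate_clinical <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- rep(names(config$group_sizes), times = config$group_sizes)
  n <- length(groups)
  out <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = groups
  )
  scores <- unique(config$clinical_moments$score)
  for (sc in scores) out[[sc]] <- NA_real_
  out$sex <- NA_integer_
  for (g in names(config$group_sizes)) {
    idx <- which(out$group == g)
    if (!length(idx)) next
    for (sc in scores) {
      row <- config$clinical_moments[
        config$clinical_moments$group == g & config$clinical_moments$score == sc,
      ]
      if (nrow(row) != 1) {
        rlang::abort(sprintf("Missing clinical moments for %s / %s.", g, sc))
      }
      out[[sc]][idx] <- rtrunc_norm_meanmatched(
        length(idx), row$mean, row$sd, row$lower, row$upper
      )
    }
    out$sex[idx] <- stats::rbinom(length(idx), 1L, config$sex_female_prop[[g]])
  }
  out[, c("subject_id", "group", "age", "sex", "education", "cdr",
          "cdr_language", "fluency_animal", "fluency_dwords", "bnt")]
}

# Separable Gaussian smoothing of a 3D array, reflecting nothing: edge
# weights renormalized by smoothing a ones-array.
smooth_field <- function(arr, sigma) {
  if (sigma < 0.5) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(seq(-r, r), sd = sigma)
  conv_axis <- function(a, axis) {
    out <- array(0, dim = dim(a))
    norm <- array(0, dim = dim(a))
    n <- dim(a)[axis]
    for (k in seq(-r, r)) {
      src <- seq_len(n) + k
      ok <- src >= 1 & src <= n
      idx_dst <- which(ok)
      idx_src <- src[ok]
      if (axis == 1) {
        out[idx_dst, , ] <- out[idx_dst, , ] + w[k + r + 1] * a[idx_src, , ]
        norm[idx_dst, , ] <- norm[idx_dst, , ] + w[k + r + 1]
      } else if (axis == 2) {
        out[, idx_dst, ] <- out[, idx_dst, ] + w[k + r + 1] * a[, idx_src, ]
        norm[, idx_dst, ] <- norm[, idx_dst, ] + w[k + r + 1]
      } else {
        out[, , idx_dst] <- out[, , idx_dst] + w[k + r + 1] * a[, , idx_src]
        norm[, , idx_dst] <- norm[, , idx_dst] + w[k + r + 1]
      }
    }
    out / norm
  }
  for (axis in 1:3) arr <- conv_axis(arr, axis)
  arr
}

#' Generate a synthetic PPA cohort
#'
#' Produces one volume per subject on a shared block parcellation, plus the
#' clinical table. Each ROI block is filled with
#' `baseline_mean + noise_sd * field`, where the field is unit-variance
#' Gaussian noise; for ROIs named in the effect spec for the subject's
#' group, the configured mean shift is added and the field is smoothed to
#' the shifted correlation length (a Gaussian random field), altering both
#' first-order and texture statistics. All other ROIs are identically
#' distributed across groups. Fully reproducible from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A `ppa_cohort`: list with `volumes` (named list of
#'   [voxel_volume()]), `mask` (shared [parcellation_mask()]), `clinical`
#'   (tibble) and `config`.
#' @export
#' @examples
#' cfg <- cohort_config(group_sizes = c(HC = 3, svPPA = 2, nfvPPA = 2),
#'                      regions = dk_regions()[1:3], seed = 7)
#' cohort <- generate_cohort(cfg)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  mask <- build_block_mask(config$regions, config$block_dim)
  clinical <- generate_clinical(config)
  rois <- mask$lookup$roi
  labels <- mask$lookup$label_id
  # precompute block voxel indices per ROI
  roi_idx <- lapply(labels, function(l) which(mask$labels == l))
  shape <- dim(mask$labels)
  nvox_block <- prod(config$block_dim)

  volumes <- vector("list", nrow(clinical))
  names(volumes) <- clinical$subject_id
  for (s in seq_len(nrow(clinical))) {
    g <- clinical$group[s]
    vol <- array(0, dim = shape)
    for (j in seq_along(rois)) {
      eff <- config$effect_spec[
        config$effect_spec$group == g & config$effect_spec$roi == rois[j],
      ]
      shift <- if (nrow(eff)) eff$mean_shift[1] else 0
      tex <- if (nrow(eff)) eff$texture_shift[1] else 1
      sigma <- config$base_corr_length * tex
      field <- array(stats::rnorm(nvox_block), dim = config$block_dim)
      if (sigma >= 0.5) {
        field <- smooth_field(field, sigma)
        field <- field / stats::sd(field)
      }
      vol[roi_idx[[j]]] <-
        config$baseline_mean + shift + config$noise_sd * as.vector(field)
    }
    volumes[[s]] <- voxel_volume(vol)
  }
  structure(
    list(volumes = volumes, mask = mask, clinical = clinical,
         config = config),
    class = "ppa_cohort"
  )
}

#' @export
print.ppa_cohort <- function(x, ...) {
  tab <- table(x$clinical$group)
  cat(sprintf(
    "<ppa_cohort> %d subjects (%s), %d ROIs, volume %s\n",
    nrow(x$clinical),
    paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
    nrow(x$mask$lookup),
    paste(dim(x$mask$labels), collapse = "x")
  ))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Volumes and the shared mask as NIfTI-1 (`.nii.gz`), the label lookup and
#' clinical table as CSV, and the generating configuration as JSON.
#'
#' @param cohort A `ppa_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ppa_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mask_nifti(cohort$mask, file.path(dir, "mask.nii.gz"),
                   file.path(dir, "labels.csv"))
  for (id in names(cohort$volumes)) {
    write_volume_nifti(cohort$volumes[[id]],
                       file.path(dir, paste0(id, ".nii.gz")))
  }
  readr::write_csv(cohort$clinical, file.path(dir, "clinical.csv"))
  cfg <- cohort$config
  jsonlite::write_json(
    list(
      group_sizes = as.list(cfg$group_sizes), regions = cfg$regions,
      block_dim = cfg$block_dim, effect_spec = cfg$effect_spec,
      baseline_mean = cfg$baseline_mean, noise_sd = cfg$noise_sd,
      base_corr_length = cfg$base_corr_length, seed = cfg$seed
    ),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
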