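# The 86-feature set: 16 first-order + 24 GLCM + 16 GLRLM + 14 GLDM +
# 16 GLSZM, computed from the raw count matrices. Feature name vectors are
# exported through feature_names() so the count contract is checkable.

fo_feature_names <- c(
  "Mean", "Median", "Minimum", "Maximum", "Range", "InterquartileRange",
  "10Percentile", "90Percentile", "Variance", "Skewness", "Kurtosis",
  "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation", "RootMeanSquared",
  "Entropy", "Uniformity"
)

glcm_feature_names <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy", "MCC",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares"
)

glrlm_feature_names <- c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LongRunHighGrayLevelEmphasis"
)

gldm_feature_names <- c(
  "SmallDependenceEmphasis", "LargeDependenceEmphasis",
  "GrayLevelNonUniformity", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "GrayLevelVariance",
  "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
  "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
  "SmallDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis",
  "LargeDependenceHighGrayLevelEmphasis"
)

glszm_feature_names <- c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis"
)

#' Names of the radiomic features, by family
#'
#' @param family One of `"firstorder"`, `"glcm"`, `"glrlm"`, `"gldm"`,
#'   `"glszm"`, or `"all"` (a named list).
#' @return Character vector of feature names (16/24/16/14/16), or a list.
#' @export
feature_names <- function(family = c("all", "firstorder", "glcm", "glrlm",
                                     "gldm", "glszm")) {
  family <- match.arg(family)
  lst <- list(
    firstorder = fo_feature_names, glcm = glcm_feature_names,
    glrlm = glrlm_feature_names, gldm = gldm_feature_names,
    glszm = glszm_feature_names
  )
  if (family == "all") lst else lst[[family]]
}

xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

# Shannon entropy (base 2) of a vector/matrix of probabilities.
ent2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' First-order intensity features of a region of interest
#'
#' The 16 first-order statistics of the within-ROI intensity distribution.
#' All are computed on the raw intensities except Entropy and Uniformity,
#' which use the discretized level histogram. Dispersion features of a
#' single-voxel ROI are 0 by convention (with a warning).
#'
#' @param roi A [discretize_roi()] result.
#' @return Named numeric vector of length 16.
#' @export
first_order_features <- function(roi) {
  v <- roi$values
  n <- length(v)
  if (n == 1L) {
    rlang::warn("Single-voxel ROI: dispersion features set to 0.")
  }
  q <- stats::quantile(v, c(0.10, 0.25, 0.5, 0.75, 0.90), names = FALSE)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  m3 <- mean((v - m)^3)
  m4 <- mean((v - m)^4)
  sub <- v[v >= q[1] & v <= q[5]]
  rmad <- if (length(sub)) mean(abs(sub - mean(sub))) else 0
  p <- tabulate(roi$levels[!is.na(roi$levels)], nbins = roi$ng) / n
  out <- c(
    Mean = m,
    Median = q[3],
    Minimum = min(v),
    Maximum = max(v),
    Range = max(v) - min(v),
    InterquartileRange = q[4] - q[2],
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Variance = m2,
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    MeanAbsoluteDeviation = mean(abs(v - m)),
    RobustMeanAbsoluteDeviation = rmad,
    RootMeanSquared = sqrt(mean(v^2)),
    Entropy = ent2(p),
    Uniformity = sum(p^2)
  )
  out[fo_feature_names]
}

# 24 GLCM features from one raw symmetric count matrix.
glcm_features_from_matrix <- function(counts) {
  ng <- nrow(counts)
  p <- counts / sum(counts)
  lev <- seq_len(ng)
  i <- .row(dim(p))
  j <- .col(dim(p))
  px <- rowSums(p)
  py <- colSums(p)
  mu_x <- sum(lev * px)
  mu_y <- sum(lev * py)
  sd_x <- sqrt(sum((lev - mu_x)^2 * px))
  sd_y <- sqrt(sum((lev - mu_y)^2 * py))
  # diagonal (i - j) and cross (i + j) probability profiles
  k_diff <- 0:(ng - 1)
  p_diff <- numeric(ng)
  agg <- rowsum(as.vector(p), as.vector(abs(i - j)))
  p_diff[as.integer(rownames(agg)) + 1L] <- agg
  k_sum <- 2:(2 * ng)
  p_sum <- numeric(2 * ng - 1)
  agg <- rowsum(as.vector(p), as.vector(i + j))
  p_sum[as.integer(rownames(agg)) - 1L] <- agg
  da <- sum(k_diff * p_diff)
  hxy <- ent2(p)
  hx <- ent2(px)
  hy <- ent2(py)
  pxpy <- outer(px, py)
  pos <- p > 0
  hxy1 <- -sum(p[pos] * log2(pxpy[pos]))
  hxy2 <- ent2(pxpy)
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- if (hxy2 > hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  # MCC: second-largest eigenvalue of Q on levels with nonzero marginals
  nz <- which(px > 0)
  mcc <- if (length(nz) < 2) {
    1
  } else {
    psub <- p[nz, nz, drop = FALSE]
    a <- sweep(sweep(psub, 1, px[nz], "/"), 2, py[nz], "/")
    q_mat <- a %*% t(psub)
    ev <- sort(Re(eigen(q_mat, only.values = TRUE)$values),
               decreasing = TRUE)
    sqrt(max(0, ev[2]))
  }
  corr <- if (sd_x * sd_y > 0) {
    (sum(i * j * p) - mu_x * mu_y) / (sd_x * sd_y)
  } else {
    1
  }
  c(
    Autocorrelation = sum(i * j * p),
    ClusterProminence = sum((i + j - mu_x - mu_y)^4 * p),
    ClusterShade = sum((i + j - mu_x - mu_y)^3 * p),
    ClusterTendency = sum((i + j - mu_x - mu_y)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = ent2(p_diff),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + (i - j)^2 / ng^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[i != j] / (i - j)[i != j]^2),
    JointAverage = mu_x,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(k_sum * p_sum),
    SumEntropy = ent2(p_sum),
    SumSquares = sum((i - mu_x)^2 * p)
  )[glcm_feature_names]
}

#' GLCM texture features of a discretized ROI
#'
#' Builds one symmetric co-occurrence matrix per direction (default: the 13
#' unique 3D directions at distance 1), computes the 24-feature set per
#' direction, and averages feature values over directions. An ROI with no
#' valid voxel pair in any direction falls back to the zero-distance limit
#' (a diagonal matrix of level probabilities) with a warning.
#'
#' @param roi A [discretize_roi()] result.
#' @param distance Pair offset in voxels.
#' @param directions Integer matrix of direction offsets (rows).
#' @return Named numeric vector of length 24.
#' @export
glcm_features <- function(roi, distance = 1L, directions = directions_3d()) {
  per_dir <- list()
  for (k in seq_len(nrow(directions))) {
    m <- glcm_matrix(roi$levels, roi$ng, directions[k, ], distance)
    if (sum(m) > 0) per_dir[[length(per_dir) + 1L]] <-
        glcm_features_from_matrix(m)
  }
  if (!length(per_dir)) {
    rlang::warn("ROI has no voxel pair in any direction; using the histogram limit.")
    h <- tabulate(roi$levels[!is.na(roi$levels)], nbins = roi$ng)
    per_dir <- list(glcm_features_from_matrix(diag(h, nrow = roi$ng)))
  }
  colMeans(do.call(rbind, per_dir))
}

# Shared kernel for the run/zone-style families: counts matrix P over
# (level i, size j), normalizer nz = sum(P), plus the voxel count for the
# percentage feature.
size_family_features <- function(counts, np) {
  nz <- sum(counts)
  i <- .row(dim(counts))
  j <- .col(dim(counts))
  p <- counts / nz
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  list(
    small = sum(counts / j^2) / nz,
    large = sum(counts * j^2) / nz,
    gln = sum(rowSums(counts)^2) / nz,
    glnn = sum(rowSums(counts)^2) / nz^2,
    sn = sum(colSums(counts)^2) / nz,
    snn = sum(colSums(counts)^2) / nz^2,
    pct = nz / np,
    glv = sum((i - mu_i)^2 * p),
    sv = sum((j - mu_j)^2 * p),
    entropy = ent2(p),
    lgl = sum(counts / i^2) / nz,
    hgl = sum(counts * i^2) / nz,
    small_lgl = sum(counts / (i^2 * j^2)) / nz,
    small_hgl = sum(counts * i^2 / j^2) / nz,
    large_lgl = sum(counts * j^2 / i^2) / nz,
    large_hgl = sum(counts * i^2 * j^2) / nz
  )
}

glrlm_features_from_matrix <- function(counts, np) {
  f <- size_family_features(counts, np)
  c(
    ShortRunEmphasis = f$small, LongRunEmphasis = f$large,
    GrayLevelNonUniformity = f$gln,
    GrayLevelNonUniformityNormalized = f$glnn,
    RunLengthNonUniformity = f$sn,
    RunLengthNonUniformityNormalized = f$snn,
    RunPercentage = f$pct, GrayLevelVariance = f$glv, RunVariance = f$sv,
    RunEntropy = f$entropy, LowGrayLevelRunEmphasis = f$lgl,
    HighGrayLevelRunEmphasis = f$hgl,
    ShortRunLowGrayLevelEmphasis = f$small_lgl,
    ShortRunHighGrayLevelEmphasis = f$small_hgl,
    LongRunLowGrayLevelEmphasis = f$large_lgl,
    LongRunHighGrayLevelEmphasis = f$large_hgl
  )[glrlm_feature_names]
}

#' GLRLM texture features of a discretized ROI
#'
#' One run-length matrix per direction (13 directions), the 16-feature set
#' per direction, averaged over directions.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 16.
#' @export
glrlm_features <- function(roi, directions = directions_3d()) {
  per_dir <- vapply(
    seq_len(nrow(directions)),
    function(k) {
      m <- glrlm_matrix(roi$levels, roi$ng, directions[k, ])
      glrlm_features_from_matrix(m, roi$n_voxels)
    },
    numeric(16)
  )
  rowMeans(per_dir)
}

#' GLDM texture features of a discretized ROI
#'
#' Dependence counts over the 26-neighborhood (Chebyshev distance
#' `distance`) with level tolerance `alpha`; a single matrix, 14 features.
#'
#' @inheritParams glcm_features
#' @param alpha Level-difference tolerance (default 0).
#' @return Named numeric vector of length 14.
#' @export
gldm_features <- function(roi, alpha = 0, distance = 1L) {
  counts <- gldm_matrix(roi$levels, roi$ng, alpha, distance)
  f <- size_family_features(counts, roi$n_voxels)
  c(
    SmallDependenceEmphasis = f$small, LargeDependenceEmphasis = f$large,
    GrayLevelNonUniformity = f$gln, DependenceNonUniformity = f$sn,
    DependenceNonUniformityNormalized = f$snn, GrayLevelVariance = f$glv,
    DependenceVariance = f$sv, DependenceEntropy = f$entropy,
    LowGrayLevelEmphasis = f$lgl, HighGrayLevelEmphasis = f$hgl,
    SmallDependenceLowGrayLevelEmphasis = f$small_lgl,
    SmallDependenceHighGrayLevelEmphasis = f$small_hgl,
    LargeDependenceLowGrayLevelEmphasis = f$large_lgl,
    LargeDependenceHighGrayLevelEmphasis = f$large_hgl
  )[gldm_feature_names]
}

#' GLSZM texture features of a discretized ROI
#'
#' Zones are 26-connected components of equal level; a single matrix (no
#' directions), 16 features.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 16.
#' @export
glszm_features <- function(roi) {
  counts <- glszm_matrix(roi$levels, roi$ng)
  f <- size_family_features(counts, roi$n_voxels)
  c(
    SmallAreaEmphasis = f$small, LargeAreaEmphasis = f$large,
    GrayLevelNonUniformity = f$gln,
    GrayLevelNonUniformityNormalized = f$glnn,
    SizeZoneNonUniformity = f$sn, SizeZoneNonUniformityNormalized = f$snn,
    ZonePercentage = f$pct, GrayLevelVariance = f$glv, ZoneVariance = f$sv,
    ZoneEntropy = f$entropy, LowGrayLevelZoneEmphasis = f$lgl,
    HighGrayLevelZoneEmphasis = f$hgl,
    SmallAreaLowGrayLevelEmphasis = f$small_lgl,
    SmallAreaHighGrayLevelEmphasis = f$small_hgl,
    LargeAreaLowGrayLevelEmphasis = f$large_lgl,
    LargeAreaHighGrayLevelEmphasis = f$large_hgl
  )[glszm_feature_names]
}
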