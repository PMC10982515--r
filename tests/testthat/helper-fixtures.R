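# Small in-code fixtures shared across test files.

# volume + single-label mask wrapping a given 3D intensity array
vol_mask_from_array <- function(arr) {
  vol <- voxel_volume(arr)
  mask <- parcellation_mask(
    array(1L, dim = dim(arr)),
    data.frame(label_id = 1L, hemisphere = "lh", region = "entorhinal")
  )
  list(volume = vol, mask = mask)
}

# a tiny cohort config for pipeline-level tests
tiny_config <- function(seed = 1, ...) {
  cohort_config(
    group_sizes = c(HC = 8, svPPA = 7, nfvPPA = 7),
    regions = c("entorhinal", "caudalmiddlefrontal"),
    seed = seed,
    ...
  )
}

# a data frame whose sample correlation matrix is exactly `target_r`
# (orthonormal scores rotated by the Cholesky factor)
exact_corr_data <- function(target_r, n = 24, seed = 1) {
  set.seed(seed)
  p <- ncol(target_r)
  z <- matrix(rnorm(n * p), n, p)
  z <- scale(z, center = TRUE, scale = FALSE)
  z <- qr.Q(qr(z))  # orthonormal and still centered
  x <- z %*% chol(target_r)
  colnames(x) <- colnames(target_r)
  tibble::as_tibble(x)
}

# linearly separable two-class table: class gap ~10 within-class SDs
separable_table <- function(n_a = 30, n_b = 24, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    group = rep(c("A", "B"), c(n_a, n_b)),
    f1 = c(rnorm(n_a, 0), rnorm(n_b, 10)),
    f2 = c(rnorm(n_a, 0), rnorm(n_b, 8)),
    noise = rnorm(n_a + n_b)
  )
}
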