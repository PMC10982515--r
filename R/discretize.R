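#' Discretize a region of interest to integer gray levels
#'
#' Extracts the voxels of one parcellation label and bins their intensities,
#' the required precondition of every IBSI texture matrix. Fixed-bin-width
#' binning assigns `level(x) = floor((x - min)/w) + 1`; fixed-bin-count uses
#' `k` equal-width bins over `[min, max]` with the maximum mapped to level
#' `k`. `Ng` is the highest observed level (empty intermediate levels are
#' retained on the gray-level axis downstream).
#'
#' @param volume A [voxel_volume()].
#' @param mask A [parcellation_mask()] on the same grid.
#' @param label_id Integer label to extract.
#' @param bin_width Fixed bin width in intensity units (default 25). Ignored
#'   when `bin_count` is given.
#' @param bin_count Optional fixed number of bins.
#' @return A `discretized_roi`: cropped 3D integer `levels` array (`NA`
#'   outside the ROI), raw intensity vector `values` (same voxel order as
#'   `which()` on the cropped array), `ng`, `n_voxels` and the binning used.
#' @export
discretize_roi <- function(volume, mask, label_id, bin_width = 25,
                           bin_count = NULL) {
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(mask, "parcellation_mask"))
  if (!identical(dim(volume$data), dim(mask$labels))) {
    rlang::abort("Volume and mask grids differ.")
  }
  idx <- which(mask$labels == label_id)
  if (!length(idx)) {
    rlang::abort(sprintf("Label %d has no voxels in the mask.", label_id))
  }
  coords <- arrayInd(idx, dim(mask$labels))
  lo <- apply(coords, 2, min)
  hi <- apply(coords, 2, max)
  sub_vol <- volume$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub_lab <- mask$labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dim(sub_vol) <- hi - lo + 1L
  dim(sub_lab) <- hi - lo + 1L
  inside <- sub_lab == label_id
  vals <- sub_vol[inside]
  vmin <- min(vals)
  vmax <- max(vals)
  if (!is.null(bin_count)) {
    k <- as.integer(bin_count)
    if (k < 1) rlang::abort("`bin_count` must be >= 1.")
    if (vmax == vmin) {
      lev <- rep(1L, length(vals))
    } else {
      w <- (vmax - vmin) / k
      lev <- pmin(k, as.integer(floor((vals - vmin) / w)) + 1L)
    }
  } else {
    if (bin_width <= 0) rlang::abort("`bin_width` must be > 0.")
    lev <- as.integer(floor((vals - vmin) / bin_width)) + 1L
  }
  levels_arr <- array(NA_integer_, dim = dim(sub_vol))
  levels_arr[inside] <- lev
  structure(
    list(
      levels = levels_arr, values = vals, ng = max(lev),
      n_voxels = length(vals),
      binning = if (is.null(bin_count)) {
        list(type = "fixed_width", bin_width = bin_width)
      } else {
        list(type = "fixed_count", bin_count = bin_count)
      }
    ),
    class = "discretized_roi"
  )
}

#' @export
print.discretized_roi <- function(x, ...) {
  cat(sprintf("<discretized_roi> %d voxels, Ng = %d\n", x$n_voxels, x$ng))
  invisible(x)
}
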