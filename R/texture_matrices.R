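# Texture matrix builders. All operate on a cropped 3D integer level array
# with NA outside the ROI (as produced by discretize_roi()) and return raw
# integer count matrices with the gray-level axis spanning 1..Ng, empty
# levels retained.

# Linear-index map for an array shift, memoized per (dims, offset): `dst`
# are the positions whose shifted source lies in bounds, `src` the matching
# source positions. ROIs share block dimensions, so the cache is hit on
# every ROI after the first.
.shift_cache <- new.env(parent = emptyenv())

shift_index <- function(dims, d) {
  key <- paste(c(dims, d), collapse = ",")
  hit <- .shift_cache[[key]]
  if (!is.null(hit)) return(hit)
  rng_dst <- lapply(1:3, function(ax) {
    from <- max(1L, 1L - d[ax])
    to <- min(dims[ax], dims[ax] - d[ax])
    if (from > to) integer() else seq.int(from, to)
  })
  if (any(vapply(rng_dst, length, 1L) == 0L)) {
    out <- list(dst = integer(), src = integer())
  } else {
    grid_dst <- as.matrix(expand.grid(rng_dst[[1]], rng_dst[[2]],
                                      rng_dst[[3]]))
    dst <- grid_dst[, 1] + (grid_dst[, 2] - 1L) * dims[1] +
      (grid_dst[, 3] - 1L) * dims[1] * dims[2]
    src <- (grid_dst[, 1] + d[1]) + (grid_dst[, 2] + d[2] - 1L) * dims[1] +
      (grid_dst[, 3] + d[3] - 1L) * dims[1] * dims[2]
    out <- list(dst = as.integer(dst), src = as.integer(src))
  }
  .shift_cache[[key]] <- out
  out
}

# Shift an array by an integer offset: out[x] = a[x + d], `fill`-padded.
shift_array <- function(a, d, fill = NA) {
  dims <- dim(a)
  idx <- shift_index(dims, d)
  out <- array(fill, dim = dims)
  out[idx$dst] <- a[idx$src]
  out
}

#' The 13 unique direction offsets of a 3D neighborhood
#'
#' One representative per +/- pair of the 26-neighborhood, the standard
#' direction set for 3D GLCM and GLRLM computation.
#'
#' @return 13 x 3 integer matrix of offsets.
#' @export
directions_3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  # keep the representative whose first nonzero component is positive
  keep <- apply(g, 1, function(v) v[which(v != 0)[1]] > 0)
  unname(g[keep, , drop = FALSE])
}

# All offsets within Chebyshev distance `dist` (26-neighborhood for dist 1).
chebyshev_offsets <- function(dist = 1L) {
  r <- -dist:dist
  g <- as.matrix(expand.grid(dx = r, dy = r, dz = r))
  unname(g[rowSums(abs(g)) > 0, , drop = FALSE])
}

#' Build a symmetric gray-level co-occurrence matrix for one direction
#'
#' Counts pairs of levels at voxel offset `d * distance`, symmetrized (each
#' unordered pair contributes to both `(i, j)` and `(j, i)`).
#'
#' @param levels Cropped level array (`NA` outside the ROI).
#' @param ng Number of gray levels.
#' @param d Integer length-3 direction offset.
#' @param distance Offset multiplier in voxels.
#' @return `ng` x `ng` integer count matrix.
#' @export
glcm_matrix <- function(levels, ng, d, distance = 1L) {
  s <- shift_array(levels, d * distance)
  ok <- !is.na(levels) & !is.na(s)
  if (!any(ok)) return(matrix(0L, ng, ng))
  i <- levels[ok]
  j <- s[ok]
  m <- matrix(tabulate((i - 1L) * ng + j, nbins = ng * ng), ng, ng,
              byrow = TRUE)
  m + t(m)
}

#' Build a gray-level run-length matrix for one direction
#'
#' A run is a maximal set of collinear voxels of equal level along `d`; the
#' matrix counts runs by `(level, run length)`.
#'
#' @inheritParams glcm_matrix
#' @param max_len Number of run-length columns (padded with zeros beyond the
#'   longest observed run); defaults to the longest run.
#' @return `ng` x `max_len` integer count matrix.
#' @export
glrlm_matrix <- function(levels, ng, d, max_len = NULL) {
  nxt <- shift_array(levels, d)
  same <- !is.na(levels) & !is.na(nxt) & levels == nxt
  prv <- shift_array(levels, -d)
  start <- !is.na(levels) & (is.na(prv) | prv != levels)
  # run length from each voxel: 1 + consecutive TRUEs of `same` along d
  rl <- array(0L, dim = dim(levels))
  rl[!is.na(levels)] <- 1L
  cur <- same
  while (any(cur)) {
    rl <- rl + cur
    cur <- cur & shift_array(cur, d, fill = FALSE)
  }
  lev <- levels[start]
  len <- rl[start]
  lmax <- if (is.null(max_len)) max(len) else max_len
  matrix(tabulate((lev - 1L) * lmax + len, nbins = ng * lmax), ng, lmax,
         byrow = TRUE)
}

#' Build the gray-level dependence matrix
#'
#' A voxel's dependence size is 1 (itself) plus the number of neighbors
#' within Chebyshev distance `distance` whose level differs by at most
#' `alpha`. The matrix counts voxels by `(level, dependence size)`.
#'
#' @inheritParams glcm_matrix
#' @param alpha Level-difference tolerance (default 0).
#' @return `ng` x max-dependence integer count matrix.
#' @export
gldm_matrix <- function(levels, ng, alpha = 0, distance = 1L) {
  offs <- chebyshev_offsets(distance)
  dep <- array(0L, dim = dim(levels))
  for (k in seq_len(nrow(offs))) {
    s <- shift_array(levels, offs[k, ])
    dep <- dep + (!is.na(s) & !is.na(levels) & abs(levels - s) <= alpha)
  }
  inside <- !is.na(levels)
  dsize <- dep[inside] + 1L
  lev <- levels[inside]
  dmax <- max(dsize)
  matrix(tabulate((lev - 1L) * dmax + dsize, nbins = ng * dmax), ng, dmax,
         byrow = TRUE)
}

# 26-connected components of equal-level voxels: iterative minimum-label
# propagation over the equal-level neighbor pair lists (within one offset
# every destination voxel is unique, so the pmin update is exact). Returns
# a component-id array (NA outside ROI).
label_zones <- function(levels) {
  dims <- dim(levels)
  dirs <- directions_3d()
  pairs <- list()
  for (k in seq_len(nrow(dirs))) {
    idx <- shift_index(dims, dirs[k, ])
    ok <- !is.na(levels[idx$dst]) & !is.na(levels[idx$src]) &
      levels[idx$dst] == levels[idx$src]
    if (any(ok)) {
      pairs[[length(pairs) + 1L]] <- list(dst = idx$dst[ok],
                                          src = idx$src[ok])
      pairs[[length(pairs) + 1L]] <- list(dst = idx$src[ok],
                                          src = idx$dst[ok])
    }
  }
  comp <- array(NA_real_, dim = dims)
  inside <- !is.na(levels)
  comp[inside] <- seq_len(sum(inside))
  repeat {
    changed <- FALSE
    for (pr in pairs) {
      nb <- comp[pr$src]
      lower <- nb < comp[pr$dst]
      if (any(lower)) {
        comp[pr$dst[lower]] <- nb[lower]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

#' Build the gray-level size-zone matrix
#'
#' Zones are 26-connected components of equal-level voxels; the matrix
#' counts zones by `(level, zone size)`.
#'
#' @inheritParams glcm_matrix
#' @return `ng` x max-zone-size integer count matrix.
#' @export
glszm_matrix <- function(levels, ng) {
  comp <- label_zones(levels)
  inside <- !is.na(levels)
  ids <- comp[inside]
  lev <- levels[inside]
  sizes <- tapply(ids, ids, length)
  zone_lev <- tapply(lev, ids, function(v) v[1])
  smax <- max(sizes)
  matrix(
    tabulate((as.integer(zone_lev) - 1L) * smax + as.integer(sizes),
             nbins = ng * smax),
    ng, smax, byrow = TRUE
  )
}
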