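# Brute-force enumeration oracles for the texture matrices, implemented as
# plain voxel loops, independent of the package's vectorized kernels.

in_bounds <- function(co, dims) all(co >= 1) && all(co <= dims)

# co-occurrence counts: loop over every voxel and both orientations of d
bf_glcm <- function(levels, ng, d, distance = 1L) {
  dims <- dim(levels)
  m <- matrix(0L, ng, ng)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) {
    for (z in seq_len(dims[3])) {
      i <- levels[x, y, z]
      if (is.na(i)) next
      for (sgn in c(1L, -1L)) {
        co <- c(x, y, z) + sgn * d * distance
        if (!in_bounds(co, dims)) next
        j <- levels[co[1], co[2], co[3]]
        if (!is.na(j)) m[i, j] <- m[i, j] + 1L
      }
    }
  }
  m
}

# run-length counts: walk every maximal run along d
bf_glrlm <- function(levels, ng, d) {
  dims <- dim(levels)
  runs <- list()
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) {
    for (z in seq_len(dims[3])) {
      i <- levels[x, y, z]
      if (is.na(i)) next
      prev <- c(x, y, z) - d
      if (in_bounds(prev, dims) &&
          !is.na(levels[prev[1], prev[2], prev[3]]) &&
          levels[prev[1], prev[2], prev[3]] == i) {
        next  # not a run start
      }
      len <- 1L
      nxt <- c(x, y, z) + d
      while (in_bounds(nxt, dims) &&
             !is.na(levels[nxt[1], nxt[2], nxt[3]]) &&
             levels[nxt[1], nxt[2], nxt[3]] == i) {
        len <- len + 1L
        nxt <- nxt + d
      }
      runs[[length(runs) + 1L]] <- c(i, len)
    }
  }
  lmax <- max(vapply(runs, `[`, 1L, 2))
  m <- matrix(0L, ng, lmax)
  for (r in runs) m[r[1], r[2]] <- m[r[1], r[2]] + 1L
  m
}

# dependence counts: per voxel, count neighbors within Chebyshev `distance`
bf_gldm <- function(levels, ng, alpha = 0, distance = 1L) {
  dims <- dim(levels)
  rows <- list()
  offs <- expand.grid(dx = -distance:distance, dy = -distance:distance,
                      dz = -distance:distance)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) {
    for (z in seq_len(dims[3])) {
      i <- levels[x, y, z]
      if (is.na(i)) next
      dep <- 1L
      for (k in seq_len(nrow(offs))) {
        co <- c(x + offs$dx[k], y + offs$dy[k], z + offs$dz[k])
        if (!in_bounds(co, dims)) next
        j <- levels[co[1], co[2], co[3]]
        if (!is.na(j) && abs(i - j) <= alpha) dep <- dep + 1L
      }
      rows[[length(rows) + 1L]] <- c(i, dep)
    }
  }
  dmax <- max(vapply(rows, `[`, 1L, 2))
  m <- matrix(0L, ng, dmax)
  for (r in rows) m[r[1], r[2]] <- m[r[1], r[2]] + 1L
  m
}

# size-zone counts: stack-based flood fill with 26-connectivity
bf_glszm <- function(levels, ng) {
  dims <- dim(levels)
  seen <- array(FALSE, dim = dims)
  zones <- list()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) {
    for (z in seq_len(dims[3])) {
      i <- levels[x, y, z]
      if (is.na(i) || seen[x, y, z]) next
      size <- 0L
      stack <- list(c(x, y, z))
      seen[x, y, z] <- TRUE
      while (length(stack)) {
        cur <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        size <- size + 1L
        for (k in seq_len(nrow(offs))) {
          co <- cur + offs[k, ]
          if (!in_bounds(co, dims) || seen[co[1], co[2], co[3]]) next
          j <- levels[co[1], co[2], co[3]]
          if (!is.na(j) && j == i) {
            seen[co[1], co[2], co[3]] <- TRUE
            stack[[length(stack) + 1L]] <- co
          }
        }
      }
      zones[[length(zones) + 1L]] <- c(i, size)
    }
  }
  smax <- max(vapply(zones, `[`, 1L, 2))
  m <- matrix(0L, ng, smax)
  for (zn in zones) m[zn[1], zn[2]] <- m[zn[1], zn[2]] + 1L
  m
}

# random discretized ROI: full box or irregular (some voxels masked out)
random_levels <- function(dims, ng, p_na = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lev <- array(sample.int(ng, prod(dims), replace = TRUE), dim = dims)
  if (p_na > 0) {
    drop <- stats::runif(prod(dims)) < p_na
    if (all(drop)) drop[1] <- FALSE
    lev[drop] <- NA_integer_
  }
  lev
}

# wrap a level array as a discretized_roi (values = levels as intensities)
roi_from_levels <- function(lev) {
  structure(
    list(levels = lev, values = as.numeric(lev[!is.na(lev)]),
         ng = max(lev, na.rm = TRUE), n_voxels = sum(!is.na(lev)),
         binning = list(type = "fixed_width", bin_width = 1)),
    class = "discretized_roi"
  )
}

# Brute-force Shapley values for an xgboost binary model, using the
# path-conditional value function on the dumped tree structure: at a split
# on a feature outside the coalition, descend both children weighted by
# training cover. Exponential in |features|; for small toy ensembles only.
bf_shapley <- function(booster, x_row, feature_names) {
  dt <- xgboost::xgb.model.dt.tree(model = booster)
  dt <- as.data.frame(dt)
  tree_value <- function(tree_df, node_id, coalition) {
    row <- tree_df[tree_df$Node == node_id, ]
    if (row$Feature == "Leaf") return(row$Gain)  # leaf value
    child_id <- function(s) as.integer(sub("^\\d+-", "", s))
    yes <- child_id(row$Yes); no <- child_id(row$No)
    if (row$Feature %in% coalition) {
      v <- x_row[[row$Feature]]
      nxt <- if (v < row$Split) yes else no
      return(tree_value(tree_df, nxt, coalition))
    }
    wy <- tree_df$Cover[tree_df$Node == yes]
    wn <- tree_df$Cover[tree_df$Node == no]
    (wy * tree_value(tree_df, yes, coalition) +
       wn * tree_value(tree_df, no, coalition)) / (wy + wn)
  }
  model_value <- function(coalition) {
    sum(vapply(unique(dt$Tree), function(tr) {
      tree_value(dt[dt$Tree == tr, ], 0L, coalition)
    }, 0))
  }
  p <- length(feature_names)
  phi <- stats::setNames(numeric(p), feature_names)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  for (f in feature_names) {
    others <- setdiff(feature_names, f)
    sub_o <- expand.grid(rep(list(c(FALSE, TRUE)), length(others)))
    for (r in seq_len(nrow(sub_o))) {
      s <- others[unlist(sub_o[r, ])]
      w <- factorial(length(s)) * factorial(p - length(s) - 1) / factorial(p)
      phi[f] <- phi[f] +
        w * (model_value(c(s, f)) - model_value(s))
    }
  }
  list(phi = phi, base = model_value(character(0)))
}
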