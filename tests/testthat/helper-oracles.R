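# Independent brute-force oracles for the texture matrices and the
# projector. Deliberately naive (triple loops, flood fill, dense matrices):
# they share no code with the package implementations.

all_26_offsets <- function() {
  out <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx || dy || dz) out[[length(out) + 1L]] <- c(dx, dy, dz)
  }
  out
}

in_grid <- function(p, d) all(p >= 1L & p <= d)

# Symmetric GLCM counts by exhaustive enumeration of ordered voxel pairs
# over all 26 offsets at the given Chebyshev distance.
oracle_glcm <- function(lev, distance = 1L) {
  d <- dim(lev)
  ng <- max(lev, na.rm = TRUE)
  M <- matrix(0, ng, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (is.na(lev[x, y, z])) next
    for (off in all_26_offsets()) {
      q <- c(x, y, z) + off * distance
      if (!in_grid(q, d)) next
      lq <- lev[q[1], q[2], q[3]]
      if (is.na(lq)) next
      M[lev[x, y, z], lq] <- M[lev[x, y, z], lq] + 1
    }
  }
  M
}

# Run-length counts per the 13-direction convention: a run starts where the
# previous voxel along the direction is absent or differs in level.
oracle_glrlm <- function(lev) {
  d <- dim(lev)
  ng <- max(lev, na.rm = TRUE)
  dirs <- Filter(function(o) {
    o[3] > 0 || (o[3] == 0 && o[2] > 0) || (o[3] == 0 && o[2] == 0 && o[1] > 0)
  }, all_26_offsets())
  runs <- list()
  for (off in dirs) {
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      l0 <- lev[x, y, z]
      if (is.na(l0)) next
      prev <- c(x, y, z) - off
      if (in_grid(prev, d) && !is.na(lev[prev[1], prev[2], prev[3]]) &&
          lev[prev[1], prev[2], prev[3]] == l0) next
      len <- 1L
      q <- c(x, y, z) + off
      while (in_grid(q, d) && !is.na(lev[q[1], q[2], q[3]]) &&
             lev[q[1], q[2], q[3]] == l0) {
        len <- len + 1L
        q <- q + off
      }
      runs[[length(runs) + 1L]] <- c(l0, len)
    }
  }
  runs <- do.call(rbind, runs)
  lmax <- max(runs[, 2])
  M <- matrix(0, ng, lmax)
  for (i in seq_len(nrow(runs))) M[runs[i, 1], runs[i, 2]] <-
      M[runs[i, 1], runs[i, 2]] + 1
  M
}

# Size zones by flood fill over 26-connectivity.
oracle_glszm <- function(lev) {
  d <- dim(lev)
  ng <- max(lev, na.rm = TRUE)
  seen <- array(FALSE, dim = d)
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (is.na(lev[x, y, z]) || seen[x, y, z]) next
    l0 <- lev[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0L
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (off in all_26_offsets()) {
        q <- p + off
        if (!in_grid(q, d)) next
        if (seen[q[1], q[2], q[3]]) next
        lq <- lev[q[1], q[2], q[3]]
        if (is.na(lq) || lq != l0) next
        seen[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1L]] <- q
      }
    }
    zones[[length(zones) + 1L]] <- c(l0, size)
  }
  zones <- do.call(rbind, zones)
  smax <- max(zones[, 2])
  M <- matrix(0, ng, smax)
  for (i in seq_len(nrow(zones))) M[zones[i, 1], zones[i, 2]] <-
      M[zones[i, 1], zones[i, 2]] + 1
  M
}

# Dependence counts: per voxel, number of 26-neighbours in the mask with
# |level difference| <= alpha.
oracle_gldm <- function(lev, alpha = 0) {
  d <- dim(lev)
  ng <- max(lev, na.rm = TRUE)
  res <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    l0 <- lev[x, y, z]
    if (is.na(l0)) next
    dep <- 0L
    for (off in all_26_offsets()) {
      q <- c(x, y, z) + off
      if (!in_grid(q, d)) next
      lq <- lev[q[1], q[2], q[3]]
      if (!is.na(lq) && abs(lq - l0) <= alpha) dep <- dep + 1L
    }
    res[[length(res) + 1L]] <- c(l0, dep)
  }
  res <- do.call(rbind, res)
  dmax <- max(res[, 2])
  M <- matrix(0, ng, dmax + 1L)
  for (i in seq_len(nrow(res))) M[res[i, 1], res[i, 2] + 1L] <-
      M[res[i, 1], res[i, 2] + 1L] + 1
  M
}

# Random discretised ROI on a small grid (levels array with NA outside).
random_lev <- function(shape, n_levels = 3L, p_mask = 0.7) {
  lev <- array(sample.int(n_levels, prod(shape), replace = TRUE),
               dim = shape)
  m <- array(runif(prod(shape)) < p_mask, dim = shape)
  if (!any(m)) m[1] <- TRUE
  lev[!m] <- NA_integer_
  # renumber so min level is 1 (matching discretise output conventions)
  lev <- lev - min(lev, na.rm = TRUE) + 1L
  lev
}

# Dense system matrix of the forward projector, built by projecting basis
# vectors one voxel at a time.
dense_projector_matrix <- function(geometry, grid) {
  nvox <- prod(dim(grid$values))
  nray <- prod(geometry$det_shape) * geometry$n_projections
  P <- matrix(0, nray, nvox)
  for (i in seq_len(nvox)) {
    e <- array(0, dim = dim(grid$values))
    e[i] <- 1
    v <- voxel_volume(e, spacing = grid$spacing, origin = grid$origin)
    P[, i] <- as.vector(forward_project(v, geometry)$data)
  }
  P
}

# Small shared fixtures -------------------------------------------------

tiny_geometry <- function() {
  build_circular_geometry(4, detector = c(4, 8, 2), sod = 30, sdd = 60)
}

tiny_grid <- function() {
  voxel_volume(array(0, dim = c(8, 8, 8)))
}

# Uniform cylinder (disc in a single slice), mu units. Boundary voxels get
# fractional coverage (8x8 supersampling) so line integrals through the
# discretized disc match the analytic chord closely at any angle.
cylinder_volume <- function(n = 64, radius = 20, mu = 0.02, ss = 8L) {
  fine <- (seq_len(n * ss) - 0.5) / ss - n / 2
  inside <- (outer(fine^2, fine^2, `+`) <= radius^2) + 0
  agg <- matrix(0, n, n * ss)
  agg[cbind(rep(seq_len(n), each = ss), seq_len(n * ss))] <- 1 / ss
  cov <- agg %*% inside %*% t(agg)
  vals <- array(mu * as.numeric(cov), dim = c(n, n, 1))
  voxel_volume(vals)
}

local_phantom_cache <- new.env(parent = emptyenv())

cached_fast_phantom <- function(seed = 1L) {
  key <- paste0("ph", seed)
  if (is.null(local_phantom_cache[[key]]))
    local_phantom_cache[[key]] <- generate_phantom(fast_phantom_spec(seed))
  local_phantom_cache[[key]]
}
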