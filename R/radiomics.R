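#' Radiomics extraction configuration
#'
#' Defaults follow the standard 3D texture-extraction settings: fixed bin
#' width 25 HU anchored at the ROI minimum, neighbour distance 1 voxel
#' (Chebyshev), symmetric co-occurrence accumulation, dependence tolerance
#' alpha 0 (a neighbour counts only when its grey level is equal), voxel
#' array shift 0, and no normalization, resampling or resegmentation.
#'
#' @param bin_width discretisation bin width in HU (> 0).
#' @param neighbor_distance neighbour distance in voxels (>= 1).
#' @param glcm_symmetric accumulate co-occurrences in both directions per
#'   angle (symmetric matrix).
#' @param gldm_alpha dependence tolerance in grey levels.
#' @param voxel_array_shift additive shift applied in energy/RMS features.
#' @return An object of class `extraction_config`.
#' @export
extraction_config <- function(bin_width = 25, neighbor_distance = 1L,
                              glcm_symmetric = TRUE, gldm_alpha = 0,
                              voxel_array_shift = 0) {
  stopifnot(bin_width > 0, neighbor_distance >= 1)
  structure(list(bin_width = bin_width,
                 neighbor_distance = as.integer(neighbor_distance),
                 glcm_symmetric = isTRUE(glcm_symmetric),
                 gldm_alpha = gldm_alpha,
                 voxel_array_shift = voxel_array_shift),
            class = "extraction_config")
}

# The 13 unique 3D direction offsets (26-neighbourhood modulo inversion)
# at Chebyshev distance 1.
offsets_13 <- function() {
  out <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0))
      out[[length(out) + 1L]] <- c(dx, dy, dz)
  }
  out
}

#' Discretise an ROI with fixed bin width
#'
#' A new bin is assigned for every intensity interval of `bin_width`
#' starting at the lowest occurring intensity in the ROI:
#' `level(x) = floor((x - min) / bin_width) + 1`.
#'
#' @param volume a [voxel_volume()].
#' @param mask a [roi_mask()] (or logical array).
#' @param config an [extraction_config()].
#' @return List with `levels` (integer array, `NA` outside the mask),
#'   `n_levels`, and `mask`.
#' @export
discretise <- function(volume, mask, config = extraction_config()) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else as.array(mask) != 0
  check_congruent(volume, m)
  if (!any(m)) stop("empty mask")
  x <- volume$values[m]
  lev <- floor((x - min(x)) / config$bin_width) + 1L
  arr <- array(NA_integer_, dim = dim(volume$values))
  arr[m] <- as.integer(lev)
  list(levels = arr, n_levels = max(lev), mask = m)
}

# Index ranges such that both x and x + o stay inside a grid of shape d;
# NULL when the offset exceeds the grid.
offset_ranges <- function(d, o) {
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, 1L - o[a]); hi <- min(d[a], d[a] - o[a])
    if (lo > hi) return(NULL)
    lo:hi
  })
  if (any(vapply(rng, is.null, TRUE))) NULL else rng
}

# For an offset, return the level pairs (a, b) of all in-mask voxel pairs
# (x, x + d * offset).
offset_pairs <- function(lev, off, distance = 1L) {
  d <- dim(lev)
  o <- off * distance
  rng <- offset_ranges(d, o)
  if (is.null(rng)) return(cbind(integer(0), integer(0)))
  xr <- rng[[1]]; yr <- rng[[2]]; zr <- rng[[3]]
  A <- lev[xr, yr, zr, drop = FALSE]
  B <- lev[xr + o[1], yr + o[2], zr + o[3], drop = FALSE]
  keep <- !is.na(A) & !is.na(B)
  cbind(A[keep], B[keep])
}

#' Grey-level co-occurrence matrix
#'
#' Counts of grey-level pairs at the 13 unique 3D offsets, aggregated over
#' directions, symmetrized (`M + t(M)`) and normalized to sum 1.
#'
#' @param disc a [discretise()] result.
#' @param config an [extraction_config()].
#' @return List with `P` (normalized matrix), `counts` (raw symmetric
#'   counts), `n_pairs` (number of ordered pairs counted).
#' @export
glcm_matrix <- function(disc, config = extraction_config()) {
  ng <- disc$n_levels
  M <- matrix(0, ng, ng)
  for (off in offsets_13()) {
    pr <- offset_pairs(disc$levels, off, config$neighbor_distance)
    if (nrow(pr))
      M <- M + matrix(tabulate((pr[, 1] - 1L) * ng + pr[, 2], ng * ng),
                      ng, ng, byrow = TRUE)
  }
  if (config$glcm_symmetric) M <- M + t(M)
  tot <- sum(M)
  P <- if (tot > 0) M / tot else M
  list(P = P, counts = M, n_pairs = tot)
}

#' Grey-level run-length matrix
#'
#' Runs of collinear equal-level voxels per direction, summed over the 13
#' unique directions. Entry `(i, j)` counts runs of level `i` and length
#' `j`.
#'
#' @param disc a [discretise()] result.
#' @return List with `counts` (matrix `n_levels` x max run length),
#'   `n_directions` (13), `n_voxels`.
#' @export
glrlm_matrix <- function(disc) {
  lev <- disc$levels
  d <- dim(lev)
  idx <- which(!is.na(lev))
  np <- length(idx)
  iz <- (idx - 1L) %/% (d[1] * d[2])
  iy <- ((idx - 1L) %/% d[1]) %% d[2]
  ix <- (idx - 1L) %% d[1]
  lv <- lev[idx]
  runs_i <- integer(0); runs_l <- integer(0)
  for (off in offsets_13()) {
    # position along the run and an id constant along each line
    t <- if (off[1] != 0) ix else if (off[2] != 0) iy else iz
    t <- t * (if (off[1] != 0) off[1] else if (off[2] != 0) off[2] else off[3])
    key <- (ix - t * off[1]) + 1e4 * (iy - t * off[2]) +
      1e8 * (iz - t * off[3])
    o <- order(key, t)
    kk <- key[o]; tt <- t[o]; ll <- lv[o]
    brk <- c(TRUE, kk[-1] != kk[-np] | tt[-1] != tt[-np] + 1L |
               ll[-1] != ll[-np])
    run_id <- cumsum(brk)
    len <- tabulate(run_id)
    runs_i <- c(runs_i, ll[brk])
    runs_l <- c(runs_l, len)
  }
  lmax <- max(runs_l)
  counts <- matrix(tabulate((runs_i - 1L) * lmax + runs_l,
                            disc$n_levels * lmax),
                   disc$n_levels, lmax, byrow = TRUE)
  list(counts = counts, n_directions = 13L, n_voxels = np)
}

#' Grey-level size-zone matrix
#'
#' Connected zones (26-connectivity) of equal grey level; entry `(i, j)`
#' counts zones of level `i` and size `j` voxels.
#'
#' @param disc a [discretise()] result.
#' @return List with `counts` (matrix `n_levels` x max zone size),
#'   `n_zones`, `n_voxels`.
#' @export
glszm_matrix <- function(disc) {
  lev <- disc$levels
  d <- dim(lev)
  pos <- array(NA_integer_, dim = d)
  idx <- which(!is.na(lev))
  np <- length(idx)
  pos[idx] <- seq_len(np)
  parent <- seq_len(np)
  for (off in offsets_13()) {
    rng <- offset_ranges(d, off)
    if (is.null(rng)) next
    xr <- rng[[1]]; yr <- rng[[2]]; zr <- rng[[3]]
    A <- pos[xr, yr, zr, drop = FALSE]
    B <- pos[xr + off[1], yr + off[2], zr + off[3], drop = FALSE]
    La <- lev[xr, yr, zr, drop = FALSE]
    Lb <- lev[xr + off[1], yr + off[2], zr + off[3], drop = FALSE]
    keep <- !is.na(A) & !is.na(B) & La == Lb
    if (!any(keep)) next
    ea <- A[keep]; eb <- B[keep]
    for (e in seq_along(ea)) {
      # union-find with path halving
      ra <- ea[e]
      while (parent[ra] != ra) {
        parent[ra] <- parent[parent[ra]]; ra <- parent[ra]
      }
      rb <- eb[e]
      while (parent[rb] != rb) {
        parent[rb] <- parent[parent[rb]]; rb <- parent[rb]
      }
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(seq_len(np), function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }, integer(1))
  sizes <- tabulate(root, np)
  zone_roots <- which(sizes > 0)
  zi <- lev[idx][zone_roots]          # level of each zone (root voxel)
  zs <- sizes[zone_roots]
  smax <- max(zs)
  counts <- matrix(tabulate((zi - 1L) * smax + zs, disc$n_levels * smax),
                   disc$n_levels, smax, byrow = TRUE)
  list(counts = counts, n_zones = length(zs), n_voxels = np)
}

#' Grey-level dependence matrix
#'
#' For each voxel, the dependence count is the number of its 26 neighbours
#' inside the mask whose grey level differs by at most `alpha` (default 0:
#' equal levels only). Entry `(i, j)` counts voxels of level `i` with
#' dependence `j - 1` (an isolated voxel has dependence 0).
#'
#' @param disc a [discretise()] result.
#' @param alpha dependence tolerance.
#' @return List with `counts` (matrix `n_levels` x (max dependence + 1)),
#'   `dependence` (integer vector of dependence values per column, from 0),
#'   `n_voxels`.
#' @export
gldm_matrix <- function(disc, alpha = 0) {
  lev <- disc$levels
  d <- dim(lev)
  dep <- array(0L, dim = d)
  for (off in offsets_13()) {
    rng <- offset_ranges(d, off)
    if (is.null(rng)) next
    xr <- rng[[1]]; yr <- rng[[2]]; zr <- rng[[3]]
    A <- lev[xr, yr, zr, drop = FALSE]
    B <- lev[xr + off[1], yr + off[2], zr + off[3], drop = FALSE]
    dependent <- !is.na(A) & !is.na(B) & abs(A - B) <= alpha
    inc <- array(0L, dim = dim(A)); inc[dependent] <- 1L
    dep[xr, yr, zr] <- dep[xr, yr, zr, drop = FALSE] + inc
    dep[xr + off[1], yr + off[2], zr + off[3]] <-
      dep[xr + off[1], yr + off[2], zr + off[3], drop = FALSE] + inc
  }
  sel <- !is.na(lev)
  lv <- lev[sel]; dp <- dep[sel]
  dmax <- max(dp)
  counts <- matrix(tabulate((lv - 1L) * (dmax + 1L) + dp + 1L,
                            disc$n_levels * (dmax + 1L)),
                   disc$n_levels, dmax + 1L, byrow = TRUE)
  list(counts = counts, dependence = 0:dmax, n_voxels = length(lv))
}

#' First-order intensity features
#'
#' The 18 default first-order statistics. Entropy and uniformity use the
#' same fixed-bin-width discretisation as the texture matrices; skewness
#' and kurtosis use biased (population) moments; kurtosis is not
#' excess-corrected. Percentiles use linear interpolation.
#'
#' @param volume a [voxel_volume()].
#' @param mask a [roi_mask()] or logical array.
#' @param config an [extraction_config()].
#' @return Named numeric vector of 18 features.
#' @export
first_order_features <- function(volume, mask, config = extraction_config()) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else as.array(mask) != 0
  check_congruent(volume, m)
  x <- volume$values[m]
  n <- length(x)
  cshift <- config$voxel_array_shift
  lev <- floor((x - min(x)) / config$bin_width) + 1L
  p <- tabulate(lev) / n
  p <- p[p > 0]
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  q <- unname(quantile(x, c(0.10, 0.25, 0.75, 0.90), type = 7))
  sel <- x >= q[1] & x <= q[4]
  energy <- sum((x + cshift)^2)
  c(Energy = energy,
    TotalEnergy = prod(volume$spacing) * energy,
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[4],
    Maximum = max(x),
    Mean = mu,
    Median = unname(stats::median(x)),
    InterquartileRange = q[3] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation =
      if (any(sel)) mean(abs(x[sel] - mean(x[sel]))) else 0,
    RootMeanSquared = sqrt(energy / n),
    Skewness = if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean((x - mu)^4) / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}

glcm_features <- function(P) {
  ng <- nrow(P)
  eps <- .Machine$double.eps
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(i * P); muy <- sum(j * P)
  varx <- sum((i - mux)^2 * P); vary <- sum((j - muy)^2 * P)
  ks <- 2:(2 * ng)
  pplus <- vapply(ks, function(k) sum(P[(i + j) == k]), 0)
  kd <- 0:(ng - 1)
  pminus <- vapply(kd, function(k) sum(P[abs(i - j) == k]), 0)
  DA <- sum(kd * pminus)
  HXY <- -sum(P * log2(P + eps))
  pxy <- outer(px, py)
  HXY1 <- -sum(P * log2(pxy + eps))
  HXY2 <- -sum(pxy * log2(pxy + eps))
  HX <- -sum(px * log2(px + eps)); HY <- -sum(py * log2(py + eps))
  denom <- max(HX, HY)
  autoc <- sum(i * j * P)
  c(Autocorrelation = autoc,
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = if (varx > 0 && vary > 0)
      (autoc - mux * muy) / sqrt(varx * vary) else 0,
    DifferenceAverage = DA,
    DifferenceEntropy = -sum(pminus * log2(pminus + eps)),
    DifferenceVariance = sum((kd - DA)^2 * pminus),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + (i - j)^2 / ng^2)),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    Imc1 = if (denom > 0) (HXY - HXY1) / denom else 0,
    Imc2 = sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY)))),
    InverseVariance = sum((P / pmax((i - j)^2, 1))[i != j]),
    JointAverage = mux,
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    MaximumProbability = max(P),
    SumEntropy = -sum(pplus * log2(pplus + eps)),
    SumSquares = varx)
}

# Shared machinery for run-length / size-zone style matrices: rows are grey
# levels i, columns a size-like index j (run length, zone size, dependence).
rl_style_features <- function(counts, jvals, Np) {
  N <- sum(counts)
  eps <- .Machine$double.eps
  i <- row(counts); jm <- matrix(jvals, nrow(counts), ncol(counts),
                                 byrow = TRUE)
  p <- counts / N
  mu_i <- sum(p * i); mu_j <- sum(p * jm)
  list(N = N, p = p, i = i, j = jm, eps = eps,
       small = sum(counts / jm^2) / N,
       large = sum(counts * jm^2) / N,
       gln = sum(rowSums(counts)^2) / N,
       jn = sum(colSums(counts)^2) / N,
       pct = N / Np,
       glv = sum(p * (i - mu_i)^2),
       jv = sum(p * (jm - mu_j)^2),
       ent = -sum(p * log2(p + eps)),
       lgl = sum(counts / i^2) / N,
       hgl = sum(counts * i^2) / N,
       small_lgl = sum(counts / (i^2 * jm^2)) / N,
       small_hgl = sum(counts * i^2 / jm^2) / N,
       large_lgl = sum(counts * jm^2 / i^2) / N,
       large_hgl = sum(counts * i^2 * jm^2) / N)
}

glrlm_features <- function(rlm) {
  s <- rl_style_features(rlm$counts, seq_len(ncol(rlm$counts)),
                         rlm$n_voxels * rlm$n_directions)
  c(ShortRunEmphasis = s$small, LongRunEmphasis = s$large,
    GrayLevelNonUniformity = s$gln,
    GrayLevelNonUniformityNormalized = s$gln / s$N,
    RunLengthNonUniformity = s$jn,
    RunLengthNonUniformityNormalized = s$jn / s$N,
    RunPercentage = s$pct,
    GrayLevelVariance = s$glv, RunVariance = s$jv, RunEntropy = s$ent,
    LowGrayLevelRunEmphasis = s$lgl, HighGrayLevelRunEmphasis = s$hgl,
    ShortRunLowGrayLevelEmphasis = s$small_lgl,
    ShortRunHighGrayLevelEmphasis = s$small_hgl,
    LongRunLowGrayLevelEmphasis = s$large_lgl,
    LongRunHighGrayLevelEmphasis = s$large_hgl)
}

glszm_features <- function(szm) {
  s <- rl_style_features(szm$counts, seq_len(ncol(szm$counts)),
                         szm$n_voxels)
  c(SmallAreaEmphasis = s$small, LargeAreaEmphasis = s$large,
    GrayLevelNonUniformity = s$gln,
    GrayLevelNonUniformityNormalized = s$gln / s$N,
    SizeZoneNonUniformity = s$jn,
    SizeZoneNonUniformityNormalized = s$jn / s$N,
    ZonePercentage = s$pct,
    GrayLevelVariance = s$glv, ZoneVariance = s$jv, ZoneEntropy = s$ent,
    LowGrayLevelZoneEmphasis = s$lgl, HighGrayLevelZoneEmphasis = s$hgl,
    SmallAreaLowGrayLevelEmphasis = s$small_lgl,
    SmallAreaHighGrayLevelEmphasis = s$small_hgl,
    LargeAreaLowGrayLevelEmphasis = s$large_lgl,
    LargeAreaHighGrayLevelEmphasis = s$large_hgl)
}

gldm_features <- function(dm) {
  # feature index j = dependence + 1, so isolated voxels contribute at j = 1
  s <- rl_style_features(dm$counts, dm$dependence + 1L, dm$n_voxels)
  c(SmallDependenceEmphasis = s$small, LargeDependenceEmphasis = s$large,
    GrayLevelNonUniformity = s$gln,
    DependenceNonUniformity = s$jn,
    DependenceNonUniformityNormalized = s$jn / s$N,
    GrayLevelVariance = s$glv, DependenceVariance = s$jv,
    DependenceEntropy = s$ent,
    LowGrayLevelEmphasis = s$lgl, HighGrayLevelEmphasis = s$hgl,
    SmallDependenceLowGrayLevelEmphasis = s$small_lgl,
    SmallDependenceHighGrayLevelEmphasis = s$small_hgl,
    LargeDependenceLowGrayLevelEmphasis = s$large_lgl,
    LargeDependenceHighGrayLevelEmphasis = s$large_hgl)
}

#' Canonical names of the 86 features
#'
#' 18 first-order, 22 co-occurrence (GLCM), 14 dependence (GLDM), 16
#' run-length (GLRLM) and 16 size-zone (GLSZM) features, in the fixed
#' canonical order used by [extract_features()]. The co-occurrence set is
#' the standard list minus the two deprecated linear duplicates
#' (dissimilarity and sum average).
#'
#' @return Character vector of length 86, values like
#'   `"firstorder_Energy"`.
#' @export
feature_names <- function() {
  dummy <- matrix(c(0.5, 0.5, 0, 0), 2, 2)
  fo <- c("Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
          "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
          "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
          "RootMeanSquared", "Skewness", "Kurtosis", "Variance",
          "Uniformity")
  c(paste0("firstorder_", fo),
    paste0("glcm_", names(glcm_features(dummy / sum(dummy)))),
    paste0("gldm_", names(gldm_features(list(counts = dummy,
                                             dependence = 0:1,
                                             n_voxels = 2)))),
    paste0("glrlm_", names(glrlm_features(list(counts = dummy,
                                               n_directions = 13L,
                                               n_voxels = 2)))),
    paste0("glszm_", names(glszm_features(list(counts = dummy,
                                               n_voxels = 2)))))
}

#' Extract the 86 radiomics features from an ROI
#'
#' Computes all first-order and texture-matrix features from `volume`
#' restricted to `mask`, using the discretisation and matrix definitions of
#' [discretise()], [glcm_matrix()], [gldm_matrix()], [glrlm_matrix()] and
#' [glszm_matrix()]. Voxel storage order never affects the result, and
#' adding a constant to the ROI leaves all texture features unchanged (the
#' binning is anchored at the ROI minimum).
#'
#' @param volume a [voxel_volume()].
#' @param mask a [roi_mask()] or logical array.
#' @param config an [extraction_config()].
#' @param acquisition_id,roi_name,tissue_class optional metadata attached
#'   as attributes.
#' @return Named numeric vector of 86 features (class `feature_vector`).
#' @export
extract_features <- function(volume, mask, config = extraction_config(),
                             acquisition_id = NA, roi_name = NULL,
                             tissue_class = NULL) {
  disc <- discretise(volume, mask, config)
  if (disc$n_levels < 2L)
    warning("single grey level in ROI; undefined features set to 0")
  fo <- first_order_features(volume, mask, config)
  gl <- glcm_features(glcm_matrix(disc, config)$P)
  gd <- gldm_features(gldm_matrix(disc, config$gldm_alpha))
  gr <- glrlm_features(glrlm_matrix(disc))
  gs <- glszm_features(glszm_matrix(disc))
  out <- c(stats::setNames(fo, paste0("firstorder_", names(fo))),
           stats::setNames(gl, paste0("glcm_", names(gl))),
           stats::setNames(gd, paste0("gldm_", names(gd))),
           stats::setNames(gr, paste0("glrlm_", names(gr))),
           stats::setNames(gs, paste0("glszm_", names(gs))))
  stopifnot(identical(names(out), feature_names()))
  if (inherits(mask, "roi_mask")) {
    roi_name <- roi_name %||% mask$name
    tissue_class <- tissue_class %||% mask$tissue_class
  }
  structure(out, class = c("feature_vector", "numeric"),
            acquisition_id = acquisition_id, roi_name = roi_name,
            tissue_class = tissue_class)
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> 86 features (roi '%s', class %s)\n",
              attr(x, "roi_name") %||% "?",
              attr(x, "tissue_class") %||% "?"))
  print(unclass(x)[1:8]); cat("  ...\n")
  invisible(x)
}
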