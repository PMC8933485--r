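#' Fit a 2-component PCA on a reference feature set
#'
#' Features are standardized (z-scored) by the reference mean and standard
#' deviation, constant features are dropped with a warning, and the first
#' two principal components are retained. Loadings are sign-fixed by making
#' each loading's largest-magnitude element positive, so fits are
#' reproducible across platforms.
#'
#' @param reference data.frame holding the feature columns (rows are
#'   acquisitions x ROIs); >= 3 rows and >= 2 non-constant features.
#' @return Object of class `pca_transform`: `features` (retained names),
#'   `center`, `scale`, `loadings` (p x 2), `explained` (variance
#'   fractions), `dropped`.
#' @export
fit_pca <- function(reference) {
  fcols <- feature_columns_or_all(reference)
  X <- as.matrix(reference[, fcols, drop = FALSE])
  if (nrow(X) < 3L) stop("PCA needs at least 3 rows")
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  keep <- sdv > 0 & is.finite(sdv)
  if (any(!keep))
    warning("dropping constant features: ",
            paste(fcols[!keep], collapse = ", "))
  if (sum(keep) < 2L) stop("need >= 2 non-constant features")
  Xs <- scale(X[, keep, drop = FALSE], center = mu[keep],
              scale = sdv[keep])
  pc <- prcomp(Xs, center = FALSE, scale. = FALSE)
  L <- pc$rotation[, 1:2, drop = FALSE]
  for (cmp in 1:2) {
    top <- which.max(abs(L[, cmp]))
    if (L[top, cmp] < 0) L[, cmp] <- -L[, cmp]
  }
  ev <- pc$sdev^2
  structure(list(features = fcols[keep], center = mu[keep],
                 scale = sdv[keep], loadings = L,
                 explained = ev[1:2] / sum(ev),
                 dropped = fcols[!keep]),
            class = "pca_transform")
}

feature_columns_or_all <- function(df) {
  fc <- feature_columns(df)
  if (length(fc)) fc else names(df)[vapply(df, is.numeric, TRUE)]
}

#' @export
print.pca_transform <- function(x, ...) {
  cat(sprintf("<pca_transform> %d features, PC1 %.1f%% / PC2 %.1f%% variance\n",
              length(x$features), 100 * x$explained[1],
              100 * x$explained[2]))
  invisible(x)
}

#' Project a feature table into a fitted PCA plane
#'
#' @param features data.frame containing (at least) the transform's feature
#'   columns.
#' @param transform a [fit_pca()] result.
#' @return data.frame with `PC1`, `PC2` plus any `roi`/`tissue_class`
#'   metadata columns carried over.
#' @export
pca_project <- function(features, transform) {
  miss <- setdiff(transform$features, names(features))
  if (length(miss))
    stop("unknown/missing features in projection input: ",
         paste(head(miss, 5), collapse = ", "))
  X <- as.matrix(features[, transform$features, drop = FALSE])
  Xs <- scale(X, center = transform$center, scale = transform$scale)
  co <- Xs %*% transform$loadings
  out <- data.frame(PC1 = co[, 1], PC2 = co[, 2])
  for (mcol in c("roi", "tissue_class", "group"))
    if (mcol %in% names(features)) out[[mcol]] <- features[[mcol]]
  out
}

#' Compare variability of two projected acquisition sets
#'
#' Per ROI label: centroid offset between the reference and test clouds,
#' per-component spread ratios (test sd / reference sd), and whether the
#' test centroid lies within the reference 95% covariance ellipse
#' (Mahalanobis distance against the chi-squared 0.95 quantile, 2 df).
#'
#' @param ref_coords,test_coords data.frames from [pca_project()] with a
#'   `roi` column.
#' @return data.frame per ROI: `roi`, `centroid_dx`, `centroid_dy`,
#'   `centroid_dist`, `sd_ratio_pc1`, `sd_ratio_pc2`, `within_ellipse`.
#' @export
compare_variability <- function(ref_coords, test_coords) {
  if (!"roi" %in% names(ref_coords) || !"roi" %in% names(test_coords))
    stop("coordinate tables need a 'roi' column")
  shared <- intersect(unique(ref_coords$roi), unique(test_coords$roi))
  only <- setdiff(union(unique(ref_coords$roi), unique(test_coords$roi)),
                  shared)
  if (length(only))
    warning("ROIs absent from one set excluded: ",
            paste(only, collapse = ", "))
  rows <- lapply(shared, function(r) {
    A <- as.matrix(ref_coords[ref_coords$roi == r, c("PC1", "PC2")])
    B <- as.matrix(test_coords[test_coords$roi == r, c("PC1", "PC2")])
    dc <- colMeans(B) - colMeans(A)
    sda <- apply(A, 2, sd); sdb <- apply(B, 2, sd)
    S <- stats::cov(A)
    within <- if (nrow(A) > 2 && all(is.finite(S)) && det(S) > 0) {
      stats::mahalanobis(colMeans(B), colMeans(A), S) <= qchisq(0.95, 2)
    } else NA
    data.frame(roi = r, centroid_dx = dc[1], centroid_dy = dc[2],
               centroid_dist = sqrt(sum(dc^2)),
               sd_ratio_pc1 = ifelse(sda[1] > 0, sdb[1] / sda[1], NA),
               sd_ratio_pc2 = ifelse(sda[2] > 0, sdb[2] / sda[2], NA),
               within_ellipse = within)
  })
  do.call(rbind, rows)
}
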