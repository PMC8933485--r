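fake_features <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(roi = rep(c("a", "b"), length.out = n),
             firstorder_Mean = rnorm(n, 50, 5),
             firstorder_Variance = rnorm(n, 100, 20),
             glcm_Contrast = rnorm(n, 2, 0.5),
             glrlm_RunEntropy = rnorm(n, 4, 1))
}

test_that("2-dimensional data is recovered exactly", {
  set.seed(30)
  df <- data.frame(roi = "a",
                   firstorder_Mean = rnorm(40),
                   firstorder_Variance = rnorm(40),
                   glcm_Contrast = 5)           # constant: dropped
  expect_warning(tr <- fit_pca(df), "constant")
  expect_equal(sum(tr$explained), 1, tolerance = 1e-12)
  expect_equal(tr$dropped, "glcm_Contrast")
  expect_error(fit_pca(df[1:2, ]), "3 rows")
})

test_that("component variances match a direct eigendecomposition", {
  df <- fake_features(60, seed = 31)
  tr <- fit_pca(df)
  X <- scale(as.matrix(df[, tr$features]))
  ev <- eigen(cov(X), symmetric = TRUE)$values
  co <- pca_project(df, tr)
  expect_equal(var(co$PC1), ev[1], tolerance = 1e-8)
  expect_equal(var(co$PC2), ev[2], tolerance = 1e-8)
  expect_equal(tr$explained, ev[1:2] / sum(ev), tolerance = 1e-8)
  # loadings orthonormal, sign convention: largest element positive
  expect_equal(crossprod(tr$loadings), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  for (k in 1:2)
    expect_gt(tr$loadings[which.max(abs(tr$loadings[, k])), k], 0)
})

test_that("projection is centred, linear, and duplicates map together", {
  df <- fake_features(50, seed = 32)
  tr <- fit_pca(df)
  co <- pca_project(df, tr)
  expect_equal(mean(co$PC1), 0, tolerance = 1e-10)
  expect_equal(mean(co$PC2), 0, tolerance = 1e-10)
  # the reference mean row projects to the origin
  mrow <- as.data.frame(as.list(tr$center))
  names(mrow) <- tr$features
  expect_equal(unlist(pca_project(mrow, tr)[, c("PC1", "PC2")]),
               c(PC1 = 0, PC2 = 0), tolerance = 1e-10)
  # +1 sd on one feature shifts coordinates by that feature's loading
  srow <- mrow
  srow[[tr$features[2]]] <- srow[[tr$features[2]]] + tr$scale[2]
  expect_equal(unname(unlist(pca_project(srow, tr)[, c("PC1", "PC2")])),
               unname(tr$loadings[2, ]), tolerance = 1e-10)
  # duplicated rows project identically
  dup <- df[c(1, 1), ]
  cd <- pca_project(dup, tr)
  expect_equal(cd[1, c("PC1", "PC2")], cd[2, c("PC1", "PC2")],
               ignore_attr = TRUE)
  expect_error(pca_project(df[, c("roi", "firstorder_Mean")], tr),
               "missing")
})

test_that("variability comparison detects shifts and spread changes", {
  df <- fake_features(120, seed = 33)
  tr <- fit_pca(df)
  co <- pca_project(df, tr)
  # identity
  cmp <- compare_variability(co, co)
  expect_equal(cmp$centroid_dist, c(0, 0), tolerance = 1e-12)
  expect_equal(cmp$sd_ratio_pc1, c(1, 1), tolerance = 1e-12)
  expect_true(all(cmp$within_ellipse))
  # pure PC1 shift
  sh <- co; sh$PC1 <- sh$PC1 + 3
  cmp2 <- compare_variability(co, sh)
  expect_equal(cmp2$centroid_dx, c(3, 3), tolerance = 1e-12)
  expect_equal(abs(cmp2$centroid_dy), c(0, 0), tolerance = 1e-12)
  expect_equal(cmp2$sd_ratio_pc2, c(1, 1), tolerance = 1e-12)
  # doubled spread
  db <- co
  db$PC1 <- db$PC1 * 2; db$PC2 <- db$PC2 * 2
  cmp3 <- compare_variability(co, db)
  expect_equal(cmp3$sd_ratio_pc1, c(2, 2), tolerance = 1e-6)
  # missing ROI excluded with warning
  expect_warning(compare_variability(co, sh[sh$roi == "a", ]), "excluded")
})
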