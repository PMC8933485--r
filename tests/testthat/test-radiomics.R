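vol_from <- function(vals) voxel_volume(array(vals, dim = dim(vals)))

test_that("fixed-bin discretisation follows the floor formula", {
  v <- voxel_volume(array(c(100, 124, 125, 150), c(4, 1, 1)))
  m <- array(TRUE, c(4, 1, 1))
  d <- discretise(v, m, extraction_config(bin_width = 25))
  expect_equal(as.vector(d$levels), c(1, 1, 2, 3))
  expect_equal(d$n_levels, 3)
  # constant ROI: single level
  vc <- voxel_volume(array(7, c(3, 3, 1)))
  dc <- discretise(vc, array(TRUE, c(3, 3, 1)))
  expect_true(all(dc$levels == 1))
  expect_equal(dc$n_levels, 1)
  expect_error(discretise(v, array(FALSE, c(4, 1, 1))), "empty")
  expect_equal(extraction_config()$bin_width, 25)
})

test_that("GLCM on a 1x3x1 strip matches exhaustive pair counting", {
  v <- voxel_volume(array(c(0, 30, 0), c(1, 3, 1)))
  m <- array(TRUE, c(1, 3, 1))
  d <- discretise(v, m)
  g <- glcm_matrix(d)
  expect_equal(g$counts, matrix(c(0, 2, 2, 0), 2, 2))
  expect_equal(g$P, matrix(c(0, 0.5, 0.5, 0), 2, 2))
})

test_that("GLCM is symmetric, normalized, and pair-conserving", {
  set.seed(10)
  for (i in 1:20) {
    lev <- random_lev(c(4, 4, 3), n_levels = 3)
    d <- list(levels = lev, n_levels = max(lev, na.rm = TRUE),
              mask = !is.na(lev))
    g <- glcm_matrix(d)
    expect_equal(g$P, t(g$P))
    if (g$n_pairs > 0) expect_equal(sum(g$P), 1)
    expect_equal(g$counts, oracle_glcm(lev))
  }
})

test_that("run-length, size-zone and dependence matrices match brute force", {
  set.seed(11)
  shapes <- list(c(4, 4, 4), c(3, 4, 2), c(4, 3, 1), c(2, 2, 2))
  n_cases <- 120
  for (i in seq_len(n_cases)) {
    shp <- shapes[[1 + (i %% length(shapes))]]
    lev <- random_lev(shp, n_levels = sample(2:3, 1))
    d <- list(levels = lev, n_levels = max(lev, na.rm = TRUE),
              mask = !is.na(lev))
    expect_equal(glrlm_matrix(d)$counts, oracle_glrlm(lev))
    expect_equal(glszm_matrix(d)$counts, oracle_glszm(lev))
    expect_equal(gldm_matrix(d)$counts, oracle_gldm(lev))
  }
})

test_that("matrix conservation laws hold", {
  set.seed(12)
  lev <- random_lev(c(5, 5, 3), n_levels = 3)
  np <- sum(!is.na(lev))
  d <- list(levels = lev, n_levels = max(lev, na.rm = TRUE),
            mask = !is.na(lev))
  rlm <- glrlm_matrix(d)
  # sum of (run length x count) over all 13 directions = 13 * voxels
  expect_equal(sum(rlm$counts %*% seq_len(ncol(rlm$counts))), 13 * np)
  szm <- glszm_matrix(d)
  expect_equal(sum(szm$counts %*% seq_len(ncol(szm$counts))), np)
  dm <- gldm_matrix(d)
  expect_equal(sum(dm$counts), np)
})

test_that("degenerate ROIs behave per contract", {
  # single voxel: one run of length 1 per direction, one zone of size 1,
  # dependence 0
  lev <- array(NA_integer_, c(3, 3, 3)); lev[2, 2, 2] <- 1L
  d <- list(levels = lev, n_levels = 1L, mask = !is.na(lev))
  rlm <- glrlm_matrix(d)
  expect_equal(sum(rlm$counts), 13)
  expect_equal(ncol(rlm$counts), 1)
  szm <- glszm_matrix(d)
  expect_equal(szm$counts, matrix(1, 1, 1))
  dm <- gldm_matrix(d)
  expect_equal(dm$dependence, 0)
  expect_equal(dm$counts, matrix(1, 1, 1))
  # 2x2x1 all one level: a single zone of size 4
  lev2 <- array(1L, c(2, 2, 1))
  d2 <- list(levels = lev2, n_levels = 1L, mask = array(TRUE, c(2, 2, 1)))
  szm2 <- glszm_matrix(d2)
  expect_equal(szm2$n_zones, 1)
  expect_equal(szm2$counts[1, 4], 1)
})

test_that("first-order features match closed forms", {
  # constant ROI
  vc <- voxel_volume(array(5, c(3, 3, 3)))
  f <- first_order_features(vc, array(TRUE, c(3, 3, 3)))
  expect_equal(unname(f["Mean"]), 5)
  expect_equal(unname(f["Variance"]), 0)
  expect_equal(unname(f["Energy"]), 27 * 25)
  expect_equal(unname(f["Entropy"]), 0)
  expect_equal(unname(f["Uniformity"]), 1)
  expect_equal(unname(f["Skewness"]), 0)
  # {1,2,3,4}
  v4 <- voxel_volume(array(1:4, c(4, 1, 1)))
  f4 <- first_order_features(v4, array(TRUE, c(4, 1, 1)))
  expect_equal(unname(f4["Mean"]), 2.5)
  expect_equal(unname(f4["Range"]), 3)
  expect_equal(unname(f4["Median"]), 2.5)
  expect_equal(unname(f4["Minimum"]), 1)
  expect_equal(unname(f4["Maximum"]), 4)
  expect_equal(unname(f4["RootMeanSquared"]), sqrt(mean((1:4)^2)))
  expect_equal(unname(f4["MeanAbsoluteDeviation"]), 1)
})

test_that("first-order features agree with a direct reference computation", {
  set.seed(13)
  x <- rnorm(500, mean = 60, sd = 25)
  v <- voxel_volume(array(x, c(10, 10, 5)))
  m <- array(TRUE, c(10, 10, 5))
  f <- first_order_features(v, m)
  mu <- mean(x); m2 <- mean((x - mu)^2)
  q <- quantile(x, c(.1, .25, .75, .9), type = 7, names = FALSE)
  expect_equal(unname(f["Variance"]), m2)
  expect_equal(unname(f["Skewness"]), mean((x - mu)^3) / m2^1.5)
  expect_equal(unname(f["Kurtosis"]), mean((x - mu)^4) / m2^2)
  expect_equal(unname(f["10Percentile"]), q[1])
  expect_equal(unname(f["InterquartileRange"]), q[3] - q[2])
  sel <- x >= q[1] & x <= q[4]
  expect_equal(unname(f["RobustMeanAbsoluteDeviation"]),
               mean(abs(x[sel] - mean(x[sel]))))
  lev <- floor((x - min(x)) / 25) + 1
  p <- tabulate(lev) / length(x); p <- p[p > 0]
  expect_equal(unname(f["Entropy"]), -sum(p * log2(p)))
  expect_equal(unname(f["Uniformity"]), sum(p^2))
})

test_that("extraction yields exactly 86 finite features in family counts", {
  ph <- cached_fast_phantom()
  fv <- extract_features(ph$volume, ph$masks[[1]])
  expect_length(fv, 86)
  fam <- table(sub("_.*", "", names(fv)))
  expect_equal(as.vector(fam[c("firstorder", "glcm", "gldm", "glrlm",
                               "glszm")]),
               c(18L, 22L, 14L, 16L, 16L))
  expect_true(all(is.finite(unclass(fv))))
  expect_identical(names(fv), feature_names())
})

test_that("features are invariant to storage order and min-anchored shift", {
  ph <- cached_fast_phantom()
  v <- ph$volume; mk <- ph$masks[[2]]
  f0 <- unclass(extract_features(v, mk))
  # permuting storage order: transpose x/y of the whole grid
  vt <- voxel_volume(aperm(v$values, c(2, 1, 3)), spacing = v$spacing)
  mt <- roi_mask(aperm(mk$mask, c(2, 1, 3)), mk$name, mk$tissue_class)
  ft <- unclass(extract_features(vt, mt))
  expect_equal(ft, f0, tolerance = 1e-12)
  # +c shift: texture features unchanged, location features shifted
  vs <- voxel_volume(v$values + 100, spacing = v$spacing)
  fs <- unclass(extract_features(vs, mk))
  tex <- grep("^(glcm|gldm|glrlm|glszm)_", names(f0), value = TRUE)
  expect_equal(fs[tex], f0[tex], tolerance = 1e-12)
  expect_equal(unname(fs["firstorder_Mean"] - f0["firstorder_Mean"]), 100)
  expect_equal(unname(fs["firstorder_Median"] - f0["firstorder_Median"]),
               100)
  expect_equal(unname(fs["firstorder_Variance"]),
               unname(f0["firstorder_Variance"]))
})

test_that("single-level ROIs produce finite features with a warning", {
  v <- voxel_volume(array(10, c(4, 4, 3)))
  m <- array(TRUE, c(4, 4, 3))
  expect_warning(fv <- extract_features(v, m), "single grey level")
  expect_true(all(is.finite(unclass(fv))))
  expect_equal(unname(unclass(fv)["glcm_Correlation"]), 0)
})
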