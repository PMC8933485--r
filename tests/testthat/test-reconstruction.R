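# A reconstruction is compared to ground truth away from the cylinder edge
# (partial-volume voxels at the boundary are not meaningful at 1 mm).
interior_rmse <- function(rec_mu, truth_mu, radius, n, margin = 2) {
  co <- (seq_len(n) - 0.5) - n / 2
  r <- sqrt(outer(co^2, co^2, `+`))
  sel <- abs(r - radius) > margin
  sqrt(mean((rec_mu[, , 1][sel] - truth_mu[, , 1][sel])^2))
}

mu_of <- function(rec) 0.0192 * (1 + rec$values / 1000)

test_that("FBP reconstructs a noiseless cylinder within 5% of contrast", {
  vol <- cylinder_volume(n = 64, radius = 20, mu = 0.02)
  g <- build_circular_geometry(450, detector = c(1, 192, 1))
  sino <- forward_project(vol, g)
  rec <- fbp_reconstruct(sino, g, recon_spec("FBP"), grid = vol)
  rmse <- interior_rmse(mu_of(rec), vol$values, 20, 64)
  expect_lt(rmse, 0.05 * 0.02)
})

test_that("FBP error shrinks as the view count grows (450 vs 150)", {
  vol <- cylinder_volume(n = 64, radius = 20, mu = 0.02)
  rmse_at <- function(nproj) {
    g <- build_circular_geometry(nproj, detector = c(1, 192, 1))
    rec <- fbp_reconstruct(forward_project(vol, g), g, recon_spec("FBP"),
                           grid = vol)
    sqrt(mean((mu_of(rec) - vol$values)^2))
  }
  expect_lt(rmse_at(450), rmse_at(150))
})

test_that("all-zero sinogram reconstructs to (numerically) zero", {
  g <- build_circular_geometry(32, detector = c(1, 96, 1))
  zero <- sinogram(array(0, c(1, 96, 32)), g, "noiseless")
  grid <- voxel_volume(array(0, c(32, 32, 1)))
  fb <- fbp_reconstruct(zero, g, recon_spec("FBP"), grid = grid)
  expect_equal(max(abs(mu_of(fb))), 0, tolerance = 1e-12)
  si <- sirt_reconstruct(zero, g, recon_spec("SIRT", n_iterations = 5),
                         grid = grid)
  expect_equal(max(abs(mu_of(si))), 0, tolerance = 1e-12)
})

test_that("SIRT residuals are non-increasing on noiseless data", {
  vol <- cylinder_volume(n = 32, radius = 10, mu = 0.02)
  g <- build_circular_geometry(48, detector = c(1, 96, 1))
  sino <- forward_project(vol, g)
  rec <- sirt_reconstruct(sino, g, recon_spec("SIRT", n_iterations = 50),
                          grid = vol)
  res <- attr(rec, "residuals")
  expect_length(res, 50)
  expect_true(all(diff(res) <= 1e-9))
})

test_that("SIRT approaches the least-squares fitted values on a dense instance", {
  g <- tiny_geometry()
  grid <- tiny_grid()
  P <- dense_projector_matrix(g, grid)
  set.seed(5)
  x_true <- runif(ncol(P), 0, 0.03)
  b <- as.vector(P %*% x_true)
  sino <- sinogram(array(b, c(g$det_shape, g$n_projections)), g,
                   "noiseless")
  rec <- sirt_reconstruct(sino, g, recon_spec("SIRT", n_iterations = 10000),
                          grid = grid)
  x_sirt <- as.vector(0.0192 * (1 + rec$values / 1000))
  fitted_sirt <- as.vector(P %*% x_sirt)
  # least-squares fitted values via the SVD pseudoinverse (rank-deficient P)
  sv <- svd(P)
  keep <- sv$d > 1e-10 * sv$d[1]
  fitted_ls <- as.vector(sv$u[, keep] %*% crossprod(sv$u[, keep], b))
  # consistent system: both fitted values must match b
  expect_lt(max(abs(fitted_sirt - b)) / max(abs(b)), 1e-3)
  expect_lt(max(abs(fitted_ls - b)) / max(abs(b)), 1e-6)
})

test_that("FBP and SIRT agree on a well-sampled noiseless phantom", {
  vol <- cylinder_volume(n = 48, radius = 15, mu = 0.02)
  g <- build_circular_geometry(300, detector = c(1, 144, 1))
  sino <- forward_project(vol, g)
  fb <- mu_of(fbp_reconstruct(sino, g, recon_spec("FBP"), grid = vol))
  si <- mu_of(sirt_reconstruct(sino, g,
                               recon_spec("SIRT", n_iterations = 200),
                               grid = vol))
  rel <- sqrt(mean((fb - si)^2)) / sqrt(mean(si^2))
  expect_lt(rel, 0.10)
})

test_that("reconstruction is deterministic", {
  vol <- cylinder_volume(n = 32, radius = 10, mu = 0.02)
  g <- build_circular_geometry(64, detector = c(1, 96, 1))
  sino <- forward_project(vol, g)
  a <- fbp_reconstruct(sino, g, recon_spec("FBP"), grid = vol)
  b <- fbp_reconstruct(sino, g, recon_spec("FBP"), grid = vol)
  expect_identical(a$values, b$values)
  s1 <- sirt_reconstruct(sino, g, recon_spec("SIRT", n_iterations = 10),
                         grid = vol)
  s2 <- sirt_reconstruct(sino, g, recon_spec("SIRT", n_iterations = 10),
                         grid = vol)
  expect_identical(s1$values, s2$values)
})

test_that("spec validation and under-determined warnings", {
  expect_error(recon_spec("SIRT", n_iterations = 0), ">= 1")
  expect_error(recon_spec("nope"), "arg")
  g1 <- build_circular_geometry(1, detector = c(1, 32, 1))
  s <- sinogram(array(0, c(1, 32, 1)), g1, "noiseless")
  grid <- voxel_volume(array(0, c(16, 16, 1)))
  expect_warning(fbp_reconstruct(s, g1, recon_spec("FBP"), grid = grid),
                 "under-determined")
})
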