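flat_sino <- function(value, n_pixels = 1e5) {
  nv <- n_pixels / 100
  g <- build_circular_geometry(nv, detector = c(1, 100, 1))
  sinogram(array(value, c(1, 100, nv)), g, "noiseless")
}

test_that("A = 0 is an exact passthrough and A < 0 is rejected", {
  s <- flat_sino(1.0, 1e3)
  out <- add_poisson_noise(s, noise_model(0, 1))
  expect_identical(out$data, s$data)
  expect_identical(out$state, "noiseless")
  expect_error(noise_model(-1e-4), ">= 0")
})

test_that("noisy sinogram variance matches the delta-method value", {
  # Var(-log(k/I0)) ~ e^I * A to first order; 1e5 pixels, 10% tolerance
  s <- flat_sino(1.0, 1e5)
  out <- add_poisson_noise(s, noise_model(1e-4, 99))
  v <- var(as.vector(out$data))
  expect_lt(abs(v - exp(1) * 1e-4) / (exp(1) * 1e-4), 0.10)
  expect_identical(out$state, "noisy")
})

test_that("the noisy mean converges to the clean line integral as A -> 0", {
  s <- flat_sino(1.0, 1e5)
  for (A in c(1e-6, 1e-5)) {
    out <- add_poisson_noise(s, noise_model(A, 5))
    se <- sqrt(exp(1) * A / 1e5)
    expect_lt(abs(mean(out$data) - 1.0), 3 * se + 1e-3 * A * exp(1))
  }
})

test_that("sample variance increases strictly with A", {
  s <- flat_sino(0.5, 1e5)
  vs <- vapply(c(5e-5, 1e-4, 2e-4, 4e-4), function(A)
    var(as.vector(add_poisson_noise(s, noise_model(A, 17))$data)), 0)
  expect_true(all(diff(vs) > 0))
})

test_that("noise is seed-deterministic and seed-sensitive", {
  s <- flat_sino(1.0, 1e4)
  a <- add_poisson_noise(s, noise_model(1e-4, 7))
  b <- add_poisson_noise(s, noise_model(1e-4, 7))
  c <- add_poisson_noise(s, noise_model(1e-4, 8))
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
})

test_that("pixelwise_variance follows its closed forms", {
  v1 <- array(1, c(4, 4, 1))
  expect_equal(pixelwise_variance(list(v1, v1, v1))$sigma2, 0)
  v2 <- v1 + 3
  pv <- pixelwise_variance(list(v1, v2))
  expect_equal(pv$sigma2, 9 / 2)                  # c^2/2 for two volumes
  expect_true(all(pv$variance_map == 9 / 2))
  expect_error(pixelwise_variance(list(v1)), "two")
  expect_error(pixelwise_variance(list(v1, array(0, c(2, 2, 1)))),
               "congruent")
})

test_that("variance-versus-A fit recovers exact lines and rejects degenerate input", {
  pts <- data.frame(A = c(0, 1, 2, 3), sigma2 = 2 * c(0, 1, 2, 3) + 1)
  fit <- fit_variance_vs_A(pts)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_lt(fit$residual, 1e-12)
  expect_error(fit_variance_vs_A(data.frame(A = c(1, 1), sigma2 = c(1, 2))),
               "degenerate")
  expect_equal(solve_A_for_variance(fit, 5), 2)
  expect_equal(solve_A_for_variance(fit, 1), 0)
  expect_error(solve_A_for_variance(fit, 0.5), "below the achievable")
  zfit <- fit
  zfit$slope <- 0
  expect_error(solve_A_for_variance(zfit, 5), "no crossing")
})

test_that("simulated calibration points have positive slope", {
  # image-domain variance is monotone in A: reconstruct tiny repetitions
  vol <- cylinder_volume(n = 32, radius = 10, mu = 0.02)
  g <- build_circular_geometry(48, detector = c(1, 96, 1))
  sino <- forward_project(vol, g)
  fit <- calibrate_noise(sino, vol, A_grid = c(5e-5, 2e-4, 8e-4), reps = 4,
                         spec = recon_spec("SIRT", n_iterations = 20),
                         base_seed = 3)
  expect_gt(fit$slope, 0)
  # seeded reruns reproduce sigma2 exactly
  fit2 <- calibrate_noise(sino, vol, A_grid = c(5e-5, 2e-4, 8e-4), reps = 4,
                          spec = recon_spec("SIRT", n_iterations = 20),
                          base_seed = 3)
  expect_equal(fit$points$sigma2, fit2$points$sigma2, tolerance = 1e-12)
})
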