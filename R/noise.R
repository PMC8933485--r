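#' Poisson noise model for sinograms
#'
#' The noise level `A` is the inverse of the background photon intensity
#' `I0` (`A = 1/I0`). For each detector pixel with ideal line integral
#' `I_image`, a photon count is sampled as `k ~ Poisson(I0 * exp(-I_image))`
#' and the noisy line integral is `-log(k / I0)`. `A = 0` means noiseless
#' passthrough. Zero counts are clamped to 1 before the log (standard
#' low-dose practice; the log of zero is undefined).
#'
#' @param A noise level (>= 0); the study default is `1e-4`.
#' @param seed integer RNG seed; draws are made pixel by pixel in
#'   column-major order from one generator, so runs are reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(A = 1e-4, seed = 1L) {
  if (!is.finite(A) || A < 0) stop("noise level A must be >= 0")
  structure(list(A = A, I0 = if (A > 0) 1 / A else Inf,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Add Poisson noise to a sinogram
#'
#' @param sino a noiseless [sinogram()].
#' @param model a [noise_model()].
#' @return A [sinogram()] with state `"noisy"` (or the input unchanged when
#'   `A = 0`).
#' @export
add_poisson_noise <- function(sino, model) {
  if (!inherits(sino, "sinogram")) stop("expected a sinogram")
  if (sino$state != "noiseless")
    stop("noise must be added to a noiseless sinogram")
  if (any(sino$data < 0)) stop("line integrals must be nonnegative")
  if (model$A == 0) return(sino)
  I0 <- model$I0
  lam <- I0 * exp(-as.numeric(sino$data))
  k <- with_seed(model$seed, rpois(length(lam), lam))
  k <- pmax(k, 1)
  out <- log(I0) - log(k)
  dim(out) <- dim(sino$data)
  sinogram(out, sino$geometry, "noisy")
}

#' Pixel-wise variance across repeated volumes
#'
#' Unbiased per-voxel variance across repetitions, averaged over a support
#' mask. This is the image-domain noise measure used for calibrating the
#' sinogram noise level.
#'
#' @param volumes list of at least two congruent [voxel_volume()]s (or bare
#'   arrays).
#' @param support optional [roi_mask()] or logical array restricting the
#'   average (default: all voxels).
#' @return List with `sigma2` (mean variance over the support) and
#'   `variance_map` (per-voxel variance array).
#' @export
pixelwise_variance <- function(volumes, support = NULL) {
  if (length(volumes) < 2L)
    stop("at least two repeated volumes are required")
  arrs <- lapply(volumes, function(v)
    if (inherits(v, "voxel_volume")) v$values else as.array(v))
  d <- dim(arrs[[1]])
  for (a in arrs) if (!identical(dim(a), d)) stop("volumes not congruent")
  n <- length(arrs)
  m <- Reduce(`+`, arrs) / n
  ss <- Reduce(`+`, lapply(arrs, function(a) (a - m)^2))
  vmap <- ss / (n - 1)
  if (is.null(support)) {
    sel <- rep(TRUE, length(vmap))
  } else {
    sel <- if (inherits(support, "roi_mask")) support$mask else support != 0
    if (!identical(dim(sel), d)) stop("support mask not congruent")
  }
  list(sigma2 = mean(vmap[sel]), variance_map = vmap)
}

#' Fit the linear variance-versus-noise-level relation
#'
#' Ordinary least squares fit `sigma2 = slope * A + intercept` through
#' calibration points; an approximately linear relation holds for the
#' Poisson sinogram noise model.
#'
#' @param points data.frame (or list of lists) with columns `A` and
#'   `sigma2`.
#' @return An object of class `calibration_fit` with `slope`, `intercept`,
#'   `residual` (RMS of residuals) and `points`.
#' @export
fit_variance_vs_A <- function(points) {
  if (!is.data.frame(points))
    points <- do.call(rbind, lapply(points, function(p)
      data.frame(A = p$A, sigma2 = p$sigma2)))
  if (any(points$sigma2 < 0)) stop("sigma2 must be >= 0")
  if (length(unique(points$A)) < 2L)
    stop("degenerate fit: need >= 2 distinct A values")
  fit <- stats::lm(sigma2 ~ A, data = points)
  co <- stats::coef(fit)
  structure(list(slope = unname(co["A"]), intercept = unname(co[1]),
                 residual = sqrt(mean(stats::resid(fit)^2)),
                 points = points),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> sigma2 = %.4g * A + %.4g (rms resid %.3g, %d points)\n",
              x$slope, x$intercept, x$residual, nrow(x$points)))
  invisible(x)
}

#' Solve the calibration line for a target variance
#'
#' Inverts the fitted line: `A = (target - intercept) / slope`. The crossing
#' point between a target image-domain variance and the fitted line guides
#' the choice of a realistic noise level.
#'
#' @param fit a [fit_variance_vs_A()] result.
#' @param target_sigma2 target mean pixel-wise variance.
#' @return The noise level `A` (>= 0).
#' @export
solve_A_for_variance <- function(fit, target_sigma2) {
  if (fit$slope == 0) stop("no crossing: fitted slope is zero")
  A <- (target_sigma2 - fit$intercept) / fit$slope
  if (A < 0)
    stop("target variance ", target_sigma2,
         " is below the achievable range (A would be negative)")
  A
}

#' Calibrate the noise level against image-domain variance
#'
#' For each noise level in `A_grid`, reconstructs `reps` noisy repetitions
#' of `sino` and computes the mean pixel-wise variance over `support`, then
#' fits the linear relation.
#'
#' @param sino noiseless [sinogram()].
#' @param grid output reconstruction grid ([voxel_volume()] template).
#' @param A_grid numeric vector of noise levels (>= 2 distinct).
#' @param reps repetitions per level (>= 2).
#' @param spec a [recon_spec()]; default SIRT.
#' @param support optional support mask for the variance average.
#' @param base_seed seed; repetition `r` at level `i` uses
#'   `base_seed + 1000 * i + r`.
#' @return A `calibration_fit`.
#' @export
calibrate_noise <- function(sino, grid, A_grid, reps = 5,
                            spec = recon_spec("SIRT", n_iterations = 50),
                            support = NULL, base_seed = 1L) {
  stopifnot(length(A_grid) >= 2L, reps >= 2L)
  pts <- lapply(seq_along(A_grid), function(i) {
    vols <- lapply(seq_len(reps), function(r) {
      noisy <- add_poisson_noise(sino, noise_model(A_grid[i],
                                                   base_seed + 1000L * i + r))
      reconstruct(noisy, spec, grid = grid)
    })
    list(A = A_grid[i], sigma2 = pixelwise_variance(vols, support)$sigma2)
  })
  fit_variance_vs_A(pts)
}
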