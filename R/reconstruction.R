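#' Reconstruction specification
#'
#' @param algorithm `"FBP"` (FDK-style filtered back-projection) or
#'   `"SIRT"` (simultaneous iterative reconstruction technique).
#' @param n_iterations SIRT iteration count (default 500, the study
#'   setting).
#' @param filter FBP detector-row filter; only `"ramp"` (Ram-Lak, no
#'   apodization) is provided — the simulator's kernel is fixed.
#' @param nonneg optional nonnegativity clamp for SIRT (default off).
#' @return An object of class `recon_spec`.
#' @export
recon_spec <- function(algorithm = c("FBP", "SIRT"), n_iterations = 500L,
                       filter = "ramp", nonneg = FALSE) {
  algorithm <- match.arg(toupper(algorithm[1]), c("FBP", "SIRT"))
  n_iterations <- as.integer(n_iterations)
  if (algorithm == "SIRT" && n_iterations < 1L)
    stop("SIRT requires n_iterations >= 1")
  filter <- match.arg(filter, "ramp")
  structure(list(algorithm = algorithm, n_iterations = n_iterations,
                 filter = filter, nonneg = isTRUE(nonneg)),
            class = "recon_spec")
}

#' Reconstruct a volume from a sinogram
#'
#' Dispatches to [fbp_reconstruct()] or [sirt_reconstruct()] according to
#' `spec$algorithm`. Output is in HU (inverse of the attenuation mapping
#' used before projection).
#'
#' @param sino a [sinogram()].
#' @param spec a [recon_spec()].
#' @param grid output grid template: a [voxel_volume()] whose shape,
#'   spacing and origin define the reconstruction grid.
#' @param model [attenuation_model()] used for the HU conversion.
#' @return A [voxel_volume()] in HU.
#' @export
reconstruct <- function(sino, spec, grid, model = attenuation_model()) {
  switch(spec$algorithm,
         FBP = fbp_reconstruct(sino, sino$geometry, spec, grid, model),
         SIRT = sirt_reconstruct(sino, sino$geometry, spec, grid, model))
}

# Band-limited Ram-Lak kernel as a length-L circular filter response.
ramp_response <- function(cols, du, L) {
  h <- numeric(L)
  h[1] <- 1 / (4 * du^2)
  k <- seq_len(cols - 1)
  hk <- ifelse(k %% 2L == 1L, -1 / (pi^2 * k^2 * du^2), 0)
  h[1 + k] <- hk
  h[L + 1 - k] <- hk
  Re(fft(h))
}

# Cosine-weight and ramp-filter a sinogram (FDK pre-processing).
# Returns an array shaped like the input; q includes the du factor.
fdk_filter <- function(data, geometry) {
  rows <- dim(data)[1]; cols <- dim(data)[2]; nv <- dim(data)[3]
  du <- sqrt(sum(geometry$u[1, ]^2)) * geometry$sod / geometry$sdd
  dv <- sqrt(sum(geometry$v[1, ]^2)) * geometry$sod / geometry$sdd
  up <- (seq_len(cols) - (cols + 1) / 2) * du
  vp <- (seq_len(rows) - (rows + 1) / 2) * dv
  w <- geometry$sod / sqrt(geometry$sod^2 +
                           outer(vp^2, up^2, `+`))      # rows x cols
  data <- data * as.vector(w)                           # recycled over views
  # filter along detector columns: bring cols to the first axis
  m <- matrix(aperm(data, c(2, 1, 3)), nrow = cols)
  L <- 2^ceiling(log2(2 * cols))
  H <- ramp_response(cols, du, L)
  pad <- rbind(m, matrix(0, L - cols, ncol(m)))
  q <- Re(mvfft(mvfft(pad) * H, inverse = TRUE)) / L
  q <- q[seq_len(cols), , drop = FALSE] * du
  aperm(array(q, dim = c(cols, rows, nv)), c(2, 1, 3))
}

#' Filtered back-projection (FDK-style) reconstruction
#'
#' Cosine-weights the projections, convolves each detector row with the
#' band-limited ramp (Ram-Lak) filter in the frequency domain, and performs
#' distance-weighted voxel-driven backprojection. For helical data at pitch
#' one this is the FDK short-object approximation. Output is converted to
#' HU.
#'
#' @inheritParams reconstruct
#' @param geometry the acquisition `proj_geometry`.
#' @return A [voxel_volume()] in HU.
#' @export
fbp_reconstruct <- function(sino, geometry = sino$geometry,
                            spec = recon_spec("FBP"), grid,
                            model = attenuation_model()) {
  if (spec$algorithm != "FBP") stop("spec$algorithm must be FBP")
  if (geometry$n_projections < 2L)
    warning("under-determined: fewer than 2 views; reconstructing anyway")
  q <- fdk_filter(sino$data, geometry)
  bp <- cpp_fdk_backproject(as.numeric(q), dim(grid$values), grid$spacing,
                            grid$origin, geometry$src, geometry$det,
                            geometry$u, geometry$v,
                            geometry$det_shape[1], geometry$det_shape[2],
                            geometry$sod, geometry$sdd)
  dbeta <- 2 * pi * geometry$n_rotations / geometry$n_projections
  mu <- voxel_volume(bp * dbeta / 2, spacing = grid$spacing,
                     origin = grid$origin)
  mu_to_hu(mu, model)
}

#' SIRT reconstruction
#'
#' Simultaneous iterative reconstruction:
#' `x_{k+1} = x_k + C * P^T * R * (b - P x_k)` with `R` and `C` the inverse
#' row and column sums of the system operator `P`, zero initialization, and
#' a fixed iteration count (default 500). Output is converted to HU.
#'
#' @inheritParams fbp_reconstruct
#' @return A [voxel_volume()] in HU. The residual norm per iteration is
#'   attached as attribute `"residuals"`.
#' @export
sirt_reconstruct <- function(sino, geometry = sino$geometry,
                             spec = recon_spec("SIRT"), grid,
                             model = attenuation_model()) {
  if (spec$algorithm != "SIRT") stop("spec$algorithm must be SIRT")
  expect_dim <- as.integer(c(geometry$det_shape, geometry$n_projections))
  if (!identical(dim(sino$data), expect_dim))
    stop("sinogram/geometry mismatch")
  fit <- cpp_sirt(as.numeric(sino$data), dim(grid$values), grid$spacing,
                  grid$origin, geometry$src, geometry$det, geometry$u,
                  geometry$v, geometry$det_shape[1], geometry$det_shape[2],
                  spec$n_iterations, spec$nonneg)
  mu <- voxel_volume(fit$x, spacing = grid$spacing, origin = grid$origin)
  out <- mu_to_hu(mu, model)
  attr(out, "residuals") <- fit$residuals
  out
}
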