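#' Sinogram container
#'
#' Stack of projection images of line integrals (dimensionless, mu in 1/mm
#' integrated over mm), stored as an array of shape
#' `(rows, cols, n_projections)` together with its generating geometry and a
#' state flag: `"noiseless"` (the ideal line integrals) or `"noisy"` (after
#' Poisson sampling).
#'
#' @param data numeric array `(rows, cols, n_views)`.
#' @param geometry the generating `proj_geometry`.
#' @param state `"noiseless"` or `"noisy"`.
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(data, geometry, state = c("noiseless", "noisy")) {
  state <- match.arg(state)
  data <- as.array(data)
  expect_dim <- c(geometry$det_shape, geometry$n_projections)
  if (!identical(dim(data), as.integer(expect_dim)))
    stop("sinogram shape ", paste(dim(data), collapse = "x"),
         " does not match geometry ", paste(expect_dim, collapse = "x"))
  if (any(!is.finite(data))) stop("sinogram data must be finite")
  structure(list(data = data, geometry = geometry, state = state),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<sinogram> %d views of %d x %d (%s), range [%.4g, %.4g]\n",
              d[3], d[1], d[2], x$state, min(x$data), max(x$data)))
  invisible(x)
}

#' Forward project an attenuation volume
#'
#' Computes, for every detector pixel of every view, the line integral of
#' the attenuation volume along the source-pixel ray using Joseph's method
#' (bilinear interpolation on the slices perpendicular to the ray's dominant
#' axis). Linear in the input volume.
#'
#' @param mu_volume attenuation [voxel_volume()] in 1/mm (see [hu_to_mu()]).
#' @param geometry a `proj_geometry`.
#' @return A [sinogram()] with state `"noiseless"`.
#' @export
forward_project <- function(mu_volume, geometry) {
  if (geometry$n_projections < 1L) stop("empty geometry")
  d <- cpp_forward_project(as.numeric(mu_volume$values),
                           dim(mu_volume$values),
                           mu_volume$spacing, mu_volume$origin,
                           geometry$src, geometry$det, geometry$u,
                           geometry$v,
                           geometry$det_shape[1], geometry$det_shape[2])
  sinogram(d, geometry, "noiseless")
}

#' Apply the adjoint of the forward projector
#'
#' Exact matrix transpose of [forward_project()] (same ray traversal, same
#' bilinear weights, scattering instead of gathering); required by SIRT.
#'
#' @param sino a [sinogram()] (or a bare array matching `geometry`).
#' @param geometry the `proj_geometry` of the sinogram.
#' @param grid a [voxel_volume()] (or list with `values`/`spacing`/`origin`)
#'   defining the output grid.
#' @return A [voxel_volume()] on `grid`.
#' @export
apply_adjoint <- function(sino, geometry, grid) {
  data <- if (inherits(sino, "sinogram")) sino$data else as.array(sino)
  expect_dim <- as.integer(c(geometry$det_shape, geometry$n_projections))
  if (!identical(dim(data), expect_dim))
    stop("sinogram/geometry mismatch: ", paste(dim(data), collapse = "x"),
         " vs ", paste(expect_dim, collapse = "x"))
  v <- cpp_backward_project(as.numeric(data), dim(grid$values),
                            grid$spacing, grid$origin,
                            geometry$src, geometry$det, geometry$u,
                            geometry$v,
                            geometry$det_shape[1], geometry$det_shape[2])
  voxel_volume(v, spacing = grid$spacing, origin = grid$origin)
}

# Empty volume on a given grid.
empty_grid <- function(shape, spacing = c(1, 1, 1), origin = NULL) {
  voxel_volume(array(0, dim = shape), spacing = spacing, origin = origin)
}
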