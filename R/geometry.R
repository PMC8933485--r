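#' Cone-beam projection geometry
#'
#' Explicit per-view vector geometry for a cone-beam scan: for each view a
#' source position, detector centre, and detector column/row axes scaled by
#' the pixel pitch. The detector centre is always diametrically opposite
#' the source through the rotation axis.
#'
#' @name proj_geometry
NULL

new_proj_geometry <- function(src, det, uvec, vvec, det_shape, sod, sdd,
                              pitch, n_rotations) {
  stopifnot(nrow(src) >= 1L, sdd > sod, sod > 0)
  g <- structure(list(src = src, det = det, u = uvec, v = vvec,
                      det_shape = as.integer(det_shape),
                      sod = sod, sdd = sdd, pitch = pitch,
                      n_rotations = n_rotations,
                      n_projections = nrow(src)),
                 class = "proj_geometry")
  # per-view axes must be orthogonal and pixels square
  du <- sqrt(rowSums(uvec^2)); dv <- sqrt(rowSums(vvec^2))
  if (max(abs(rowSums(uvec * vvec))) > 1e-9 * max(du * dv))
    stop("detector axes not orthogonal")
  if (max(abs(du - dv)) > 1e-9 * max(du))
    stop("detector pixels must be square")
  g
}

#' @export
print.proj_geometry <- function(x, ...) {
  cat(sprintf(paste0("<proj_geometry> %d views, detector %d x %d ",
                     "(%.3g mm px), sod %.4g mm, sdd %.4g mm, pitch %.3g\n"),
              x$n_projections, x$det_shape[1], x$det_shape[2],
              sqrt(sum(x$u[1, ]^2)), x$sod, x$sdd, x$pitch))
  invisible(x)
}

#' Build a helical cone-beam geometry
#'
#' Views are uniform in gantry angle on a half-open grid (view `i` of `n`
#' gets fraction `i/n` of the total angular span), and the source advances
#' linearly in z so that one full rotation advances the table by
#' `pitch * rows * pixel_mm * sod / sdd` (the detector height projected to
#' the isocenter). The number of rotations is chosen to cover
#' `[z_start, z_end]`.
#'
#' @param n_projections total number of views (>= 1).
#' @param z_start,z_end source z range to cover, mm.
#' @param detector `c(rows, cols, pixel_mm)`; default `c(512, 512, 1)`.
#' @param sod source-to-isocenter distance, mm (default 500).
#' @param sdd source-to-detector distance, mm (default 1000).
#' @param pitch helical pitch (default 1).
#' @param angle0 starting gantry angle, radians.
#' @return A `proj_geometry`.
#' @export
build_helical_geometry <- function(n_projections, z_start, z_end,
                                   detector = c(512, 512, 1),
                                   sod = 500, sdd = 1000, pitch = 1,
                                   angle0 = 0) {
  n_projections <- as.integer(n_projections)
  if (is.na(n_projections) || n_projections < 1L)
    stop("n_projections must be >= 1")
  if (z_end <= z_start) stop("z_end must exceed z_start")
  rows <- detector[1]; cols <- detector[2]; px <- detector[3]
  advance <- pitch * rows * px * sod / sdd     # table feed per rotation, mm
  n_rot <- (z_end - z_start) / advance
  if (n_rot < 1 / n_projections)
    warning(sprintf("z-range %.3g mm is far below one view's advance;",
                    z_end - z_start), " achieved coverage is degenerate")
  i <- seq_len(n_projections) - 1
  ang <- angle0 + 2 * pi * n_rot * i / n_projections
  z <- z_start + (z_end - z_start) * i / n_projections
  helical_vectors(ang, z, rows, cols, px, sod, sdd, pitch, n_rot)
}

#' Build a circular (pitch 0) cone-beam geometry
#'
#' Single-rotation scan at fixed source z; with a one-row detector and a
#' single-slice volume this is the package's 2D fan-beam "fast mode".
#'
#' @param n_projections number of views over a full rotation.
#' @param z source/detector z position, mm.
#' @param detector `c(rows, cols, pixel_mm)`.
#' @inheritParams build_helical_geometry
#' @return A `proj_geometry`.
#' @export
build_circular_geometry <- function(n_projections, z = 0,
                                    detector = c(1, 256, 1),
                                    sod = 500, sdd = 1000, angle0 = 0) {
  n_projections <- as.integer(n_projections)
  if (is.na(n_projections) || n_projections < 1L)
    stop("n_projections must be >= 1")
  rows <- detector[1]; cols <- detector[2]; px <- detector[3]
  i <- seq_len(n_projections) - 1
  ang <- angle0 + 2 * pi * i / n_projections
  helical_vectors(ang, rep(z, n_projections), rows, cols, px, sod, sdd,
                  pitch = 0, n_rot = 1)
}

helical_vectors <- function(ang, z, rows, cols, px, sod, sdd, pitch, n_rot) {
  # source at angle a: (-sod cos a, -sod sin a, z); detector centre opposite
  src <- unname(cbind(-sod * cos(ang), -sod * sin(ang), z))
  det <- unname(cbind((sdd - sod) * cos(ang), (sdd - sod) * sin(ang), z))
  uvec <- cbind(-sin(ang), cos(ang), 0) * px     # detector column axis
  vvec <- cbind(0, 0, 1)[rep(1, length(ang)), , drop = FALSE] * px  # row axis
  new_proj_geometry(src, det, uvec, vvec, c(rows, cols), sod, sdd, pitch,
                    n_rot)
}

#' Serialize a geometry to JSON (per-view 12-component vectors)
#'
#' @param geometry a `proj_geometry`.
#' @param path output JSON path.
#' @return `path` invisibly; `read_geometry` returns a `proj_geometry`.
#' @export
write_geometry <- function(geometry, path) {
  vecs <- cbind(geometry$src, geometry$det, geometry$u, geometry$v)
  jsonlite::write_json(
    list(det_shape = geometry$det_shape, sod = geometry$sod,
         sdd = geometry$sdd, pitch = geometry$pitch,
         n_rotations = geometry$n_rotations, vectors = vecs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- matrix(as.numeric(x$vectors), ncol = 12)
  new_proj_geometry(v[, 1:3, drop = FALSE], v[, 4:6, drop = FALSE],
                    v[, 7:9, drop = FALSE], v[, 10:12, drop = FALSE],
                    x$det_shape, x$sod, x$sdd, x$pitch, x$n_rotations)
}

#' Attenuation model for HU conversion
#'
#' Linear HU scale: `mu = mu_water * (1 + HU/1000)`, clamped at zero.
#'
#' @param mu_water linear attenuation of water in 1/mm (default 0.0192).
#' @return An object of class `attenuation_model`.
#' @export
attenuation_model <- function(mu_water = 0.0192) {
  stopifnot(is.finite(mu_water), mu_water > 0)
  structure(list(mu_water = mu_water), class = "attenuation_model")
}

#' Convert a HU volume to linear attenuation (1/mm)
#'
#' @param volume a [voxel_volume()] in HU.
#' @param model an [attenuation_model()].
#' @return A [voxel_volume()] whose values are attenuation coefficients.
#' @export
hu_to_mu <- function(volume, model = attenuation_model()) {
  mu <- pmax(model$mu_water * (1 + volume$values / 1000), 0)
  voxel_volume(mu, spacing = volume$spacing, origin = volume$origin)
}

#' Convert an attenuation volume back to HU
#'
#' @param volume attenuation [voxel_volume()] in 1/mm.
#' @param model an [attenuation_model()].
#' @return A [voxel_volume()] in HU.
#' @export
mu_to_hu <- function(volume, model = attenuation_model()) {
  hu <- 1000 * (volume$values / model$mu_water - 1)
  voxel_volume(hu, spacing = volume$spacing, origin = volume$origin)
}
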