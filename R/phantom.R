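#' Phantom specification
#'
#' Describes a synthetic abdominal phantom: an elliptical soft-tissue body on
#' a background at the lower printable limit (-100 HU), plus a set of
#' ellipsoidal tissue regions of interest. Each region has a mean HU, a
#' texture amplitude (the standard deviation, in HU, of a spatially
#' correlated Gaussian field) and a texture correlation length in mm. All
#' HU values are confined to the printable range [-100, 1000].
#'
#' @param shape integer length-3 grid shape (nx, ny, nz).
#' @param spacing voxel spacing in mm.
#' @param body list with `semi_axes` (mm), `mean_hu`, `amplitude`,
#'   `corr_mm`.
#' @param rois list of ROI descriptors; each a list with `name`,
#'   `tissue_class`, `center` (mm, relative to the volume centre), `radii`
#'   (mm, length 3), `mean_hu`, `amplitude`, `corr_mm`.
#' @param background_hu background value, default -100 (printable minimum).
#' @param seed integer RNG seed; the generator is fully deterministic given
#'   the seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, spacing = c(1, 1, 1), body, rois,
                         background_hu = -100, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) == 2L) shape <- c(shape, 1L)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  spec <- structure(list(shape = shape, spacing = spacing, body = body,
                         rois = rois, background_hu = background_hu,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  lohi <- c(-100, 1000)
  chk <- function(mean_hu, amp, what) {
    if (mean_hu - amp < lohi[1] || mean_hu + amp > lohi[2])
      stop(what, ": mean ", mean_hu, " +/- amplitude ", amp,
           " HU falls outside the printable range [-100, 1000]")
  }
  chk(spec$body$mean_hu, spec$body$amplitude, "body")
  for (r in spec$rois) chk(r$mean_hu, r$amplitude, paste0("ROI '", r$name, "'"))
  if (spec$background_hu < lohi[1] || spec$background_hu > lohi[2])
    stop("background HU outside the printable range [-100, 1000]")
  cls <- vapply(spec$rois, `[[`, "", "tissue_class")
  if (!all(cls %in% tissue_classes()))
    stop("unknown tissue class: ", paste(setdiff(cls, tissue_classes()),
                                         collapse = ", "))
  invisible(spec)
}

#' Default 3D phantom specification
#'
#' Six ellipsoidal ROIs in four tissue classes (two normal liver regions,
#' two cysts, one hemangioma, one metastasis) inside an elliptical body, on
#' a 128 x 128 x 64 grid at 1 mm isotropic spacing.
#'
#' @param seed RNG seed.
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(seed = 1L) {
  phantom_spec(
    shape = c(128L, 128L, 64L), spacing = c(1, 1, 1),
    body = list(semi_axes = c(52, 44, 30), mean_hu = 30, amplitude = 10,
                corr_mm = 3),
    rois = default_rois(scale = 1),
    seed = seed
  )
}

#' Fast single-slice phantom specification
#'
#' A 64 x 64 x 1 "2D mode" version of [default_phantom_spec()], used by the
#' fast circular-scan pipeline and the test suite. ROI discs keep the same
#' four tissue classes and class-distinct HU means.
#'
#' @param seed RNG seed.
#' @return A [phantom_spec()].
#' @export
fast_phantom_spec <- function(seed = 1L) {
  phantom_spec(
    shape = c(64L, 64L, 1L), spacing = c(1, 1, 1),
    body = list(semi_axes = c(28, 24, Inf), mean_hu = 30, amplitude = 10,
                corr_mm = 3),
    rois = default_rois(scale = 0.5, radius = 5, flat = TRUE),
    seed = seed
  )
}

default_rois <- function(scale = 1, radius = 8, flat = FALSE) {
  ctr <- function(x, y) {
    z <- 0
    c(x, y, z) * c(scale, scale, 1)
  }
  rad <- if (flat) c(radius, radius, Inf) else rep(radius, 3)
  mk <- function(name, cls, x, y, mean_hu, amp)
    list(name = name, tissue_class = cls, center = ctr(x, y), radii = rad,
         mean_hu = mean_hu, amplitude = amp, corr_mm = 3)
  list(
    mk("liver_1",    "normal_liver", -26, -14, 60, 12),
    mk("liver_2",    "normal_liver", -26,  14, 60, 12),
    mk("cyst_1",     "cyst",           0, -24,  5,  6),
    mk("cyst_2",     "cyst",           0,  24,  5,  6),
    mk("hemangioma", "hemangioma",    24, -12, 140, 20),
    mk("metastasis", "metastasis",    24,  14, 33, 15)
  )
}

# World coordinates of voxel centres relative to the volume centre.
grid_coords <- function(shape, spacing) {
  lapply(1:3, function(a) {
    (seq_len(shape[a]) - 0.5) * spacing[a] - shape[a] * spacing[a] / 2
  })
}

ellipsoid_mask <- function(shape, spacing, center, radii) {
  co <- grid_coords(shape, spacing)
  fx <- ((co[[1]] - center[1]) / radii[1])^2
  fy <- ((co[[2]] - center[2]) / radii[2])^2
  fz <- ((co[[3]] - center[3]) / radii[3])^2   # radii of Inf contribute 0
  outer(outer(fx, fy, `+`), fz, `+`) <= 1
}

# Periodic Gaussian smoothing via FFT; sigma per axis in voxels.
smooth_gaussian_fft <- function(arr, sigma_vox) {
  d <- dim(arr)
  h1 <- axis_gauss(d[1], sigma_vox[1])
  h2 <- axis_gauss(d[2], sigma_vox[2])
  h3 <- axis_gauss(d[3], sigma_vox[3])
  H <- array(outer(outer(h1, h2), h3), dim = d)
  Re(fft(fft(arr) * H, inverse = TRUE)) / prod(d)
}

axis_gauss <- function(n, sigma) {
  if (n == 1L) return(1)
  f <- (seq_len(n) - 1)
  f <- ifelse(f > n / 2, f - n, f) / n
  exp(-2 * pi^2 * sigma^2 * f^2)
}

# Correlated unit-variance Gaussian field over the full grid.
correlated_field <- function(shape, spacing, corr_mm, seed) {
  with_seed(seed, {
    noise <- array(rnorm(prod(shape)), dim = shape)
    sigma_vox <- corr_mm / spacing
    sigma_vox[shape == 1L] <- 0
    sm <- smooth_gaussian_fft(noise, sigma_vox)
    s <- sd(as.vector(sm))
    if (s == 0) sm else sm / s
  })
}

#' Generate a synthetic phantom
#'
#' Realises a [phantom_spec()] as a HU volume plus one [roi_mask()] per
#' region. Texture is a seeded, spatially correlated Gaussian random field
#' (periodic FFT smoothing to the requested correlation length), scaled to
#' the region's amplitude and added to its mean HU. The realised volume is
#' clamped to the printable range [-100, 1000] HU (Gaussian tails beyond the
#' stated amplitude are rare but unbounded).
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (a [voxel_volume()]) and `masks`
#'   (list of [roi_mask()]).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  shape <- spec$shape; spacing <- spec$spacing
  body_mask <- ellipsoid_mask(shape, spacing, c(0, 0, 0),
                              spec$body$semi_axes)
  roi_masks <- lapply(spec$rois, function(r)
    ellipsoid_mask(shape, spacing, r$center, r$radii))
  n_roi <- length(roi_masks)
  if (n_roi >= 2) {
    for (i in seq_len(n_roi - 1)) for (j in (i + 1):n_roi) {
      if (any(roi_masks[[i]] & roi_masks[[j]]))
        stop("overlapping ROIs: '", spec$rois[[i]]$name, "' and '",
             spec$rois[[j]]$name, "'")
    }
  }
  for (i in seq_len(n_roi)) {
    if (!any(roi_masks[[i]]) || any(roi_masks[[i]] & !body_mask))
      stop("ROI '", spec$rois[[i]]$name, "' extends outside the body region")
  }
  vals <- array(spec$background_hu, dim = shape)
  bodyf <- correlated_field(shape, spacing, spec$body$corr_mm, spec$seed)
  vals[body_mask] <- spec$body$mean_hu +
    spec$body$amplitude * bodyf[body_mask]
  for (i in seq_len(n_roi)) {
    r <- spec$rois[[i]]
    f <- correlated_field(shape, spacing, r$corr_mm, spec$seed + 1000L * i)
    vals[roi_masks[[i]]] <- r$mean_hu + r$amplitude * f[roi_masks[[i]]]
  }
  vals <- pmin(pmax(vals, -100), 1000)
  vol <- voxel_volume(vals, spacing = spacing)
  masks <- lapply(seq_len(n_roi), function(i)
    roi_mask(roi_masks[[i]], name = spec$rois[[i]]$name,
             tissue_class = spec$rois[[i]]$tissue_class))
  list(volume = vol, masks = masks)
}

#' Read or write a phantom spec as JSON
#'
#' @param spec a [phantom_spec()].
#' @param path JSON file path.
#' @return `read_phantom_spec` returns a [phantom_spec()];
#'   `write_phantom_spec` returns `path` invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  rois <- lapply(x$rois, function(r) {
    r$center <- as.numeric(r$center)
    r$radii <- as.numeric(r$radii)
    r
  })
  phantom_spec(shape = x$shape, spacing = x$spacing, body = x$body,
               rois = rois, background_hu = x$background_hu, seed = x$seed)
}
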