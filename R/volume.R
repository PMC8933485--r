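#' Voxel volume container
#'
#' A 3D scalar grid in Hounsfield units (HU) with voxel spacing and world
#' origin. World coordinates follow the voxel-centre convention used
#' throughout the package: the centre of voxel `(i, j, k)` (0-based) sits at
#' `origin + (index + 0.5) * spacing`.
#'
#' @param values 3D numeric array of HU values.
#' @param spacing numeric length-3, voxel edge lengths in mm (dx, dy, dz).
#' @param origin numeric length-3, world position (mm) of the corner of the
#'   first voxel.
#' @return An object of class `voxel_volume` with fields `values`, `spacing`,
#'   `origin`.
#' @export
voxel_volume <- function(values, spacing = c(1, 1, 1), origin = NULL) {
  values <- as.array(values)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L)
    stop("voxel_volume requires a 3D array, got ", length(dim(values)), "D")
  if (any(dim(values) < 1L)) stop("all volume dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite numbers")
  if (is.null(origin)) origin <- -dim(values) * spacing / 2
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers")
  if (any(!is.finite(values))) stop("volume values must be finite")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  HU range [%.1f, %.1f], origin (%s) mm\n",
              min(x$values), max(x$values),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$values)

#' Region-of-interest mask
#'
#' A binary mask congruent with a [voxel_volume()], labelled with a name and
#' one of the four tissue classes used in the phantom.
#'
#' @param mask 3D logical (or coercible) array, same shape as the volume it
#'   annotates.
#' @param name label string.
#' @param tissue_class one of `"normal_liver"`, `"cyst"`, `"hemangioma"`,
#'   `"metastasis"`.
#' @param min_voxels minimum number of `TRUE` voxels (default 27, the
#'   smallest ROI on which all 3D texture directions are defined).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, name, tissue_class, min_voxels = 27L) {
  mask <- as.array(mask) != 0
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  if (length(dim(mask)) != 3L) stop("ROI mask must be a 3D array")
  n <- sum(mask)
  if (n == 0L) stop("empty ROI: mask '", name, "' has no voxels")
  if (n < min_voxels)
    stop("ROI '", name, "' has ", n, " voxels; minimum is ", min_voxels)
  tissue_class <- match.arg(tissue_class, tissue_classes())
  structure(list(mask = mask, name = as.character(name),
                 tissue_class = tissue_class),
            class = "roi_mask")
}

#' The four phantom tissue classes
#' @return Character vector of class labels.
#' @export
tissue_classes <- function() {
  c("normal_liver", "cyst", "hemangioma", "metastasis")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s' (%s): %d voxels\n", x$name, x$tissue_class,
              sum(x$mask)))
  invisible(x)
}

check_congruent <- function(volume, mask) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  if (!identical(dim(volume$values), dim(m)))
    stop("mask shape (", paste(dim(m), collapse = "x"),
         ") does not match volume shape (",
         paste(dim(volume$values), collapse = "x"), ")")
  invisible(TRUE)
}
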