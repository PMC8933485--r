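# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
#
# Only what the package needs: 3D scalar volumes, axis-aligned orientation
# (diagonal sform), little-endian files. The world convention used by the
# rest of the package places the corner of the first voxel at `origin`;
# NIfTI's affine maps 0-based indices to voxel centres, so the stored offset
# is origin + spacing/2.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2, signed = FALSE)   # uint16
)

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a volume to a NIfTI-1 file
#'
#' @param volume a [voxel_volume()] (or a [roi_mask()], stored as uint8).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param datatype `"float64"` (default, lossless round trip) or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, datatype = c("float64", "uint8")) {
  datatype <- match.arg(datatype)
  if (inherits(volume, "roi_mask"))
    stop("write_mask() writes roi_mask objects")
  if (!inherits(volume, "voxel_volume")) stop("expected a voxel_volume")
  nifti_write_array(volume$values, volume$spacing, volume$origin, path,
                    datatype)
  invisible(path)
}

#' Write an ROI mask to a NIfTI-1 file (uint8)
#'
#' @param mask a [roi_mask()].
#' @param volume the companion [voxel_volume()] providing spacing/origin.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, volume, path) {
  check_congruent(volume, mask)
  nifti_write_array(mask$mask + 0, volume$spacing, volume$origin, path,
                    "uint8")
  invisible(path)
}

nifti_write_array <- function(arr, spacing, origin, path, datatype) {
  dt <- switch(datatype, float64 = 64L, uint8 = 2L)
  bitpix <- switch(datatype, float64 = 64L, uint8 = 8L)
  d <- dim(arr)
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(s, len) {
    r <- raw(len)
    b <- charToRaw(s)
    if (length(b) > 0) r[seq_along(b)] <- b
    writeBin(r, con)
  }
  off <- origin + spacing / 2              # NIfTI offset = first voxel centre
  wi(348, 4)                               # sizeof_hdr
  writeBin(raw(36), con)                   # data_type..dim_info (unused)
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)          # dim[8]
  wf(c(0, 0, 0)); wi(0, 2)                 # intent_p*, intent_code
  wi(dt, 2); wi(bitpix, 2); wi(0, 2)       # datatype, bitpix, slice_start
  wf(c(1, spacing, 1, 1, 1, 1))            # pixdim[8] (qfac = 1)
  wf(352)                                  # vox_offset
  wf(1); wf(0)                             # scl_slope, scl_inter
  wi(0, 2); writeBin(raw(1), con)          # slice_end, slice_code
  writeBin(as.raw(2L), con)                # xyzt_units: mm
  wf(c(0, 0, 0, 0))                        # cal_max/min, slice_dur, toffset
  wi(c(0L, 0L), 4)                         # glmax, glmin
  wc("radphantom", 80); wc("", 24)         # descrip, aux_file
  wi(0, 2); wi(1, 2)                       # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0))                           # quatern b, c, d
  wf(off)                                  # qoffset x, y, z
  wf(c(spacing[1], 0, 0, off[1]))          # srow_x
  wf(c(0, spacing[2], 0, off[2]))          # srow_y
  wf(c(0, 0, spacing[3], off[3]))          # srow_z
  wc("", 16)                               # intent_name
  wc("n+1", 4)                             # magic
  writeBin(raw(4), con)                    # no extensions
  if (datatype == "float64") {
    writeBin(as.numeric(arr), con, size = 8, endian = "little")
  } else {
    writeBin(as.integer(arr), con, size = 1, endian = "little")
  }
  invisible(path)
}

nifti_read_header <- function(con) {
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("not a NIfTI-1 file: header truncated")
  ri <- function(at, size, n = 1, signed = TRUE)
    readBin(hdr[(at + 1):(at + size * n)], "integer", n = n, size = size,
            signed = signed, endian = "little")
  rf <- function(at, n = 1)
    readBin(hdr[(at + 1):(at + 4 * n)], "double", n = n, size = 4,
            endian = "little")
  if (ri(0, 4) != 348L)
    stop("not a little-endian NIfTI-1 file (sizeof_hdr != 348)")
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic string")
  list(dim = ri(40, 2, 8), datatype = ri(70, 2), bitpix = ri(72, 2),
       pixdim = rf(76, 8), vox_offset = rf(108),
       scl_slope = rf(112), scl_inter = rf(116),
       qform_code = ri(252, 2), sform_code = ri(254, 2),
       qoffset = rf(268, 3),
       srow = rbind(rf(280, 4), rf(296, 4), rf(312, 4)))
}

#' Read a 3D NIfTI-1 volume
#'
#' Supports little-endian single-file NIfTI-1 (optionally gzipped) with an
#' axis-aligned orientation. Intensity scaling (`scl_slope`/`scl_inter`) is
#' applied.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  h <- nifti_read_header(con)
  ndim <- h$dim[1]
  if (ndim != 3L)
    stop("format error: expected 3D NIfTI data, got ", ndim, "D")
  d <- h$dim[2:4]
  dt <- NIFTI_DTYPES[[as.character(h$datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", h$datatype)
  skip <- h$vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(d)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = "little")
  if (length(vals) < n) stop("NIfTI data truncated")
  if (h$scl_slope != 0 && !(h$scl_slope == 1 && h$scl_inter == 0))
    vals <- vals * h$scl_slope + h$scl_inter
  dim(vals) <- d
  spacing <- h$pixdim[2:4]
  if (h$sform_code > 0) {
    m <- h$srow[, 1:3]
    if (max(abs(m - diag(diag(m)))) > 1e-4 * max(abs(m)) || any(diag(m) <= 0))
      stop("only axis-aligned (diagonal, positive) sforms are supported")
    spacing <- diag(m)
    centre0 <- h$srow[, 4]
  } else if (h$qform_code > 0) {
    centre0 <- h$qoffset
  } else {
    centre0 <- spacing / 2 - d * spacing / 2
  }
  voxel_volume(vals, spacing = spacing, origin = centre0 - spacing / 2)
}

#' Read an ROI mask from a NIfTI-1 file
#'
#' Nonzero voxels become `TRUE`. The mask grid must be congruent with the
#' companion volume.
#'
#' @param path path to the mask file.
#' @param volume the [voxel_volume()] the mask annotates.
#' @param name label for the ROI (default: file name).
#' @param tissue_class tissue class label, see [tissue_classes()].
#' @return A [roi_mask()].
#' @export
read_mask <- function(path, volume, name = NULL,
                      tissue_class = "normal_liver") {
  v <- read_volume(path)
  if (!identical(dim(v$values), dim(volume$values)))
    stop("congruence error: mask grid ",
         paste(dim(v$values), collapse = "x"), " vs volume ",
         paste(dim(volume$values), collapse = "x"))
  name <- name %||% sub("\\.nii(\\.gz)?$", "", basename(path))
  if (!any(v$values != 0)) stop("empty ROI: ", path)
  roi_mask(v$values != 0, name = name, tissue_class = tissue_class)
}
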