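#' Minimal NIfTI-1 reader and writer
#'
#' Self-contained single-file NIfTI-1 support (.nii, .nii.gz) sufficient for
#' dynamic images, masks and parameter maps: 3D/4D volumes, common numeric
#' datatypes, scl_slope/scl_inter scaling, and the srow affine.  Not a
#' general NIfTI library (no extensions, no .hdr/.img pairs).
#'
#' @name nifti
NULL

.nifti_dtypes <- list(
  `2` = list(what = "integer", size = 1, signed = FALSE),   # uint8
  `4` = list(what = "integer", size = 2, signed = TRUE),    # int16
  `8` = list(what = "integer", size = 4, signed = TRUE),    # int32
  `16` = list(what = "double", size = 4, signed = TRUE),    # float32
  `64` = list(what = "double", size = 8, signed = TRUE),    # float64
  `512` = list(what = "integer", size = 2, signed = FALSE)) # uint16

.open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' @param path .nii or .nii.gz file.
#' @return list: \code{data} (array), \code{voxel_size_mm},
#'   \code{affine} (4x4), \code{dim}.
#' @export
read_nifti <- function(path) {
  con <- .open_maybe_gz(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1, 4)
  endian <- "little"
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- .swap_int(sizeof_hdr)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
  }
  readBin(con, "raw", 36)                      # unused header fields
  dims <- readBin(con, "integer", 8, 2, endian = endian)
  readBin(con, "raw", 14)
  datatype <- readBin(con, "integer", 1, 2, endian = endian)
  readBin(con, "integer", 1, 2, endian = endian)  # bitpix
  readBin(con, "integer", 1, 2, endian = endian)  # slice_start
  pixdim <- readBin(con, "numeric", 8, 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, 4, endian = endian)
  scl_slope <- readBin(con, "numeric", 1, 4, endian = endian)
  scl_inter <- readBin(con, "numeric", 1, 4, endian = endian)
  readBin(con, "raw", 252 - 120)               # slice/cal fields, descrip, aux_file
  readBin(con, "integer", 2, 2, endian = endian)        # qform, sform codes
  readBin(con, "numeric", 6, 4, endian = endian)        # quaternions/offsets
  srow <- matrix(readBin(con, "numeric", 12, 4, endian = endian),
                 3, 4, byrow = TRUE)
  readBin(con, "raw", 16)                      # intent_name
  magic <- rawToChar(readBin(con, "raw", 4))
  if (!grepl("^n\\+1", magic)) stop("only single-file NIfTI-1 supported")
  ndim <- dims[1]
  shape <- dims[2:(1 + max(ndim, 1))]
  shape <- shape[shape > 0]
  dt <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(shape)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed, endian = endian)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  affine <- rbind(srow, c(0, 0, 0, 1))
  if (all(srow == 0)) {
    affine <- diag(c(pixdim[2:4], 1))
  }
  list(data = array(as.numeric(vals), shape),
       voxel_size_mm = abs(pixdim[2:4]), affine = affine, dim = shape)
}

.swap_int <- function(x) {
  b <- writeBin(as.integer(x), raw(), size = 4)
  readBin(rev(b), "integer", 1, 4)
}

#' Write a NIfTI-1 volume (float32, single file)
#'
#' @param data 3D or 4D numeric array.
#' @param path output .nii or .nii.gz file.
#' @param voxel_size_mm voxel edges, mm.
#' @param affine optional 4x4 voxel-to-world matrix; default diagonal from
#'   the voxel size.
#' @param frame_dt_s frame durations for the 4th-axis pixdim (optional).
#' @export
write_nifti <- function(data, path, voxel_size_mm = c(1, 1, 1),
                        affine = NULL, frame_dt_s = 1) {
  d <- dim(data)
  if (is.null(d)) stop("data must be an array")
  ndim <- length(d)
  if (!ndim %in% c(3L, 4L)) stop("only 3D/4D volumes supported")
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  dims <- integer(8); dims[1] <- ndim; dims[2:(1 + ndim)] <- d
  dims[dims == 0] <- 1L
  pixdim <- numeric(8)
  pixdim[1] <- 1
  pixdim[2:4] <- voxel_size_mm
  if (ndim == 4L) pixdim[5] <- frame_dt_s[1]
  con <- .open_maybe_gz(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, 4)
  writeBin(raw(36), con)
  writeBin(as.integer(dims), con, 2)
  writeBin(raw(14), con)
  writeBin(16L, con, 2)                      # float32
  writeBin(32L, con, 2)                      # bitpix
  writeBin(0L, con, 2)                       # slice_start
  writeBin(pixdim, con, 4)
  writeBin(352, con, 4)                      # vox_offset
  writeBin(1, con, 4)                        # scl_slope
  writeBin(0, con, 4)                        # scl_inter
  writeBin(raw(252 - 120), con)
  writeBin(c(0L, 2L), con, 2)                # qform = 0, sform = aligned
  writeBin(numeric(6), con, 4)
  writeBin(as.numeric(t(affine[1:3, ])), con, 4)
  writeBin(raw(16), con)
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)
  writeBin(raw(4), con)                      # pad to 352
  writeBin(as.numeric(data), con, 4)
  invisible(path)
}

#' Read a 4D dynamic image with schedule validation
#'
#' @param path 4D NIfTI file.
#' @param schedule a \code{frame_schedule}; frame count must match.
#' @param mask optional 3D NIfTI mask path or logical array.
#' @return a \code{dynamic_image}.
#' @export
read_dynamic <- function(path, schedule, mask = NULL) {
  nii <- read_nifti(path)
  d <- nii$dim
  if (length(d) != 4L)
    stop("expected a 4D image, got ", length(d), "D")
  if (d[4] != schedule$J)
    stop(sprintf("image has %d frames but the schedule has %d", d[4], schedule$J))
  if (!is.null(mask) && is.character(mask)) {
    m <- read_nifti(mask)$data
    mask <- array(m != 0, dim(m))
  }
  img <- dynamic_image(nii$data, schedule, voxel_size_mm = nii$voxel_size_mm,
                       mask = mask)
  img$affine <- nii$affine
  img
}
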