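# Minimal NIfTI-1 I/O. No NIfTI reader is available in the installed R
# stack, so the format is handled directly: fixed 348-byte header, optional
# gzip wrapping, sform/qform affines, common datatypes, scl_slope/inter
# scaling. Intentionally limited to 3-D volumes (the only inputs the
# pipeline accepts).

NIFTI_HDR_SIZE <- 348L

nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "numeric", size = 4L, signed = TRUE),
  `64` = list(what = "numeric", size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

#' Load a NIfTI volume
#'
#' Reads a 3-D NIfTI-1 image (`.nii` or `.nii.gz`) into a [volume_grid].
#' The affine is taken from the sform if present, else the qform, else a
#' diagonal affine from `pixdim`; voxel spacing is derived from the affine
#' column norms. Intensities are kept in native units (after applying
#' `scl_slope`/`scl_inter` when set); no rescaling is done at load.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [volume_grid].
#' @export
load_volume <- function(path) {
  if (!file.exists(path))
    stop("load_volume: file not found: ", path, call. = FALSE)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", NIFTI_HDR_SIZE)
  if (length(hdr_raw) < NIFTI_HDR_SIZE)
    stop("load_volume: truncated NIfTI header in ", path, call. = FALSE)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1, 4, endian = endian)
  if (sizeof_hdr != NIFTI_HDR_SIZE) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1, 4, endian = endian)
    if (sizeof_hdr != NIFTI_HDR_SIZE)
      stop("load_volume: not a NIfTI-1 file: ", path, call. = FALSE)
  }
  rd_i16 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 2 * n)],
                                     "integer", n, 2, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4 * n)],
                                     "numeric", n, 4, endian = endian)
  dims <- rd_i16(40, 8)
  ndim <- dims[1]
  if (ndim > 3L && any(dims[(4 + 1):(ndim + 1)] > 1L))
    stop("load_volume: expected a 3-D image, got ", ndim, "-D: ", path,
         call. = FALSE)
  if (ndim < 3L)
    stop("load_volume: expected a 3-D image, got ", ndim, "-D: ", path,
         call. = FALSE)
  shape <- pmax(dims[2:4], 1L)
  datatype <- rd_i16(70, 1)
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt))
    stop("load_volume: unsupported NIfTI datatype code ", datatype,
         call. = FALSE)
  pixdim <- rd_f32(76, 8)
  vox_offset <- rd_f32(108, 1)
  scl_slope <- rd_f32(112, 1)
  scl_inter <- rd_f32(116, 1)
  qform_code <- rd_i16(252, 1)
  sform_code <- rd_i16(254, 1)

  if (sform_code > 0) {
    affine <- rbind(rd_f32(280, 4), rd_f32(296, 4), rd_f32(312, 4),
                    c(0, 0, 0, 1))
  } else if (qform_code > 0) {
    q <- rd_f32(256, 3) # quatern b, c, d
    qoff <- rd_f32(268, 3)
    a2 <- 1 - sum(q^2)
    a <- if (a2 < 0) 0 else sqrt(a2)
    b <- q[1]; cc <- q[2]; d <- q[3]
    R <- matrix(c(
      a * a + b * b - cc * cc - d * d, 2 * (b * cc - a * d), 2 * (b * d + a * cc),
      2 * (b * cc + a * d), a * a + cc * cc - b * b - d * d, 2 * (cc * d - a * b),
      2 * (b * d - a * cc), 2 * (cc * d + a * b), a * a + d * d - b * b - cc * cc),
      3, 3, byrow = TRUE)
    qfac <- if (pixdim[1] < 0) -1 else 1
    sp <- abs(pixdim[2:4])
    R <- R %*% diag(c(sp[1], sp[2], qfac * sp[3]))
    affine <- rbind(cbind(R, qoff), c(0, 0, 0, 1))
  } else {
    affine <- diag(c(abs(pixdim[2:4]), 1))
  }

  # skip to voxel data
  skip <- max(vox_offset, NIFTI_HDR_SIZE) - NIFTI_HDR_SIZE
  if (skip > 0) readBin(con, "raw", as.integer(skip))
  n <- prod(shape)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n)
    stop("load_volume: truncated voxel data in ", path, call. = FALSE)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  volume_grid(array(vals, dim = shape), affine = affine)
}

#' Write a volume as NIfTI-1
#'
#' Writes a [volume_grid] to `.nii` (or `.nii.gz` when the path ends in
#' `.gz`) as float64 with the affine stored in the sform (code 2).
#'
#' @param vol a [volume_grid].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  validate_volume_grid(vol)
  shape <- dim(vol$data)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, 2, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348)                       # sizeof_hdr
  w_raw(36)                        # data_type..dim_info
  w_i16(c(3, shape, 1, 1, 1, 1))   # dim
  w_f32(c(0, 0, 0)); w_i16(0)      # intent
  w_i16(64); w_i16(64)             # datatype float64, bitpix
  w_i16(0)                         # slice_start
  w_f32(c(1, vol$spacing, 1, 1, 1, 1)) # pixdim (qfac 1)
  w_f32(352)                       # vox_offset
  w_f32(1); w_f32(0)               # scl_slope, scl_inter
  w_i16(0); w_raw(2)               # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))             # cal_max..toffset
  w_i32(c(0, 0))                   # glmax, glmin
  w_raw(80 + 24)                   # descrip, aux_file
  w_i16(0); w_i16(2)               # qform_code 0, sform_code 2
  w_f32(rep(0, 6))                 # quatern, qoffset
  w_f32(vol$affine[1, ])           # srow_x
  w_f32(vol$affine[2, ])           # srow_y
  w_f32(vol$affine[3, ])           # srow_z
  w_raw(16)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  w_raw(4)                         # extension indicator
  writeBin(as.numeric(vol$data), con, 8, endian = "little")
  invisible(path)
}
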