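# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
# Only what the pipeline needs: 3D volumes, float/int datatypes, pixdim
# voxel sizes and an sform affine.  No R package in this stack reads NIfTI,
# so the format is implemented here against the NIfTI-1 header layout.

NII_HDR_SIZE <- 348L
NII_VOX_OFFSET <- 352

.nii_datatypes <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

.nii_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D volume as a NIfTI-1 file
#'
#' Writes a single-file NIfTI-1 volume (`.nii`, or gzip-compressed when the
#' path ends in `.nii.gz`). The affine is stored in the sform; when omitted it
#' is a diagonal scaling by the voxel size with zero origin.
#'
#' @param data 3D numeric array of voxel values.
#' @param path Output file path ending in `.nii` or `.nii.gz`.
#' @param voxel_size_mm Numeric length-3 voxel spacing in mm.
#' @param affine Optional 4x4 voxel-to-world matrix (row-major sform rows).
#' @param datatype Storage type, `"float32"` (default) or `"float64"`.
#' @return The path, invisibly.
#' @export
nifti_write <- function(data, path, voxel_size_mm, affine = NULL,
                        datatype = "float32") {
  if (length(dim(data)) != 3L) stop("nifti_write expects a 3D array")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  dt <- .nii_datatypes[[match.arg(datatype, c("float32", "float64"))]]
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- voxel_size_mm
  }
  stopifnot(all(dim(affine) == c(4L, 4L)))

  con <- .nii_con(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_chr <- function(n) writeBin(raw(n), con)

  w_i32(NII_HDR_SIZE)                    # sizeof_hdr
  w_chr(28L)                             # data_type, db_name
  w_i32(0L); w_i16(0L); w_chr(2L)        # extents, session_error, regular, dim_info
  w_i16(c(3L, dim(data), 1L, 1L, 1L, 1L))  # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)           # intent_p1-3, intent_code
  w_i16(dt$code); w_i16(dt$bitpix); w_i16(0L)  # datatype, bitpix, slice_start
  w_f32(c(0, voxel_size_mm, 0, 0, 0, 0)) # pixdim[8]
  w_f32(NII_VOX_OFFSET)                  # vox_offset
  w_f32(1); w_f32(0)                     # scl_slope, scl_inter
  w_i16(0L); w_chr(1L)                   # slice_end, slice_code
  writeBin(as.raw(2L), con)              # xyzt_units: mm
  w_f32(c(0, 0, 0, 0))                   # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                       # glmax, glmin
  w_chr(80L); w_chr(24L)                 # descrip, aux_file
  w_i16(0L); w_i16(1L)                   # qform_code, sform_code
  w_f32(rep(0, 6))                       # quatern b/c/d, qoffset x/y/z
  w_f32(affine[1, ]); w_f32(affine[2, ]); w_f32(affine[3, ])  # srow_x/y/z
  w_chr(16L)                             # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  w_i32(0L)                              # 4-byte extension flag -> offset 352

  if (dt$what == "double") {
    writeBin(as.numeric(data), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.integer(round(data)), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 volume (optionally gzipped). Handles the common
#' integer and float datatypes, both byte orders, and applies the scl
#' slope/intercept when set.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with `data` (3D array), `voxel_size_mm` and `affine`.
#' @export
nifti_read <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  con <- .nii_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = NII_HDR_SIZE)
  if (length(hdr) < NII_HDR_SIZE) stop(sprintf("not a NIfTI-1 file (truncated header): %s", path))
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (sz != NII_HDR_SIZE) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (sz != NII_HDR_SIZE) stop(sprintf("not a NIfTI-1 file: %s", path))
  }
  r_i16 <- function(off, n) readBin(hdr[(off + 1):(off + 2L * n)], "integer",
                                    n = n, size = 2L, endian = endian)
  r_f32 <- function(off, n) readBin(hdr[(off + 1):(off + 4L * n)], "double",
                                    n = n, size = 4L, endian = endian)
  dims <- r_i16(40L, 8L)
  ndim <- dims[1]
  if (ndim < 3L) stop(sprintf("expected a 3D volume: %s", path))
  shape <- dims[2:4]
  if (ndim > 3L && any(dims[5:(1 + ndim)] > 1L))
    stop(sprintf("expected a single 3D volume, got %dD data: %s", ndim, path))
  dtcode <- r_i16(70L, 1L)
  dt_idx <- vapply(.nii_datatypes, function(d) d$code, integer(1)) == dtcode
  if (!any(dt_idx)) stop(sprintf("unsupported NIfTI datatype code %d: %s", dtcode, path))
  dt <- .nii_datatypes[[which(dt_idx)]]
  pixdim <- r_f32(76L, 8L)
  vox_offset <- r_f32(108L, 1L)
  scl_slope <- r_f32(112L, 1L)
  scl_inter <- r_f32(116L, 1L)
  sform_code <- r_i16(254L, 1L)
  affine <- diag(4)
  if (sform_code > 0L) {
    affine[1, ] <- r_f32(280L, 4L)
    affine[2, ] <- r_f32(296L, 4L)
    affine[3, ] <- r_f32(312L, 4L)
  } else {
    diag(affine)[1:3] <- pixdim[2:4]
  }

  skip <- round(vox_offset) - NII_HDR_SIZE
  if (skip > 0L) readBin(con, "raw", n = skip)
  nvox <- prod(shape)
  vals <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < nvox) stop(sprintf("truncated NIfTI data: %s", path))
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(as.numeric(vals), dim = shape),
       voxel_size_mm = abs(pixdim[2:4]),
       affine = affine)
}
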