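# Minimal NIfTI-1 reader/writer.
#
# The sandboxed analysis stack ships no R neuroimaging I/O package, so the
# package carries a small, self-contained NIfTI-1 implementation: single-file
# .nii (optionally gzipped), little-endian, sform affine, float32/float64 and
# common integer datatypes. This is deliberately not a general-purpose NIfTI
# library; it covers exactly what the pipeline writes and reads back.

NIFTI_DT <- list(
  uint8 = list(code = 2L, bitpix = 8L, what = "integer", size = 1L, signed = FALSE),
  int16 = list(code = 4L, bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32 = list(code = 8L, bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "numeric", size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "numeric", size = 8L, signed = TRUE)
)

nifti_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D or 4D array as a NIfTI-1 volume
#'
#' Little-endian single-file NIfTI-1 with the affine stored in the sform.
#' Spatial units are mm, temporal units seconds.
#'
#' @param data numeric array with 3 or 4 dimensions.
#' @param path output file; `.nii` or `.nii.gz`.
#' @param affine 4x4 voxel-to-world matrix (1-based voxel indices are
#'   converted to the 0-based NIfTI convention internally).
#' @param datatype one of `"float32"`, `"float64"`, `"int16"`, `"int32"`,
#'   `"uint8"`.
#' @param tr_s repetition time stored in `pixdim[4]`, seconds.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = centered_affine(dim(data)[1:3], 1),
                        datatype = "float32", tr_s = 0) {
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stopf("write_nifti: data must be 3D or 4D")
  dt <- NIFTI_DT[[datatype]]
  if (is.null(dt)) stopf("write_nifti: unsupported datatype '%s'", datatype)
  d <- dim(data)
  dim8 <- c(nd, d, rep(1L, 7 - length(d)))
  # sform rows; NIfTI voxel indices are 0-based -> shift the translation
  a0 <- affine
  a0[1:3, 4] <- affine[1:3, 4] + affine[1:3, 1:3] %*% rep(1, 3)
  voxdim <- sqrt(colSums(affine[1:3, 1:3]^2))

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)

  wi(348L, 4)                          # sizeof_hdr
  wraw(10 + 18 + 4 + 2 + 1 + 1)        # data_type..dim_info
  wi(dim8, 2)                          # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)            # intent_p1-3, intent_code
  wi(dt$code, 2); wi(dt$bitpix, 2)     # datatype, bitpix
  wi(0L, 2)                            # slice_start
  wf(c(1, voxdim, tr_s, 0, 0, 0))      # pixdim[8] (qfac = 1)
  wf(352)                              # vox_offset
  wf(1); wf(0)                         # scl_slope, scl_inter
  wi(0L, 2)                            # slice_end
  writeBin(as.raw(c(0L, 10L)), con)    # slice_code, xyzt_units (mm | sec)
  wf(c(0, 0, 0, 0))                    # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                     # glmax, glmin
  wraw(80 + 24)                        # descrip, aux_file
  wi(0L, 2); wi(1L, 2)                 # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))             # quaternions + qoffsets
  wf(a0[1, ]); wf(a0[2, ]); wf(a0[3, ])
  wraw(16)                             # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)
  wraw(4)                              # extension flag
  storage <- if (dt$what == "integer") as.integer(round(data)) else as.numeric(data)
  writeBin(storage, con, size = dt$size, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_nifti()]
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (array), `affine` (4x4, 1-based voxel
#'   convention), `voxel_mm`, `tr_s`, `datatype`.
#' @export
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  skip <- function(n) readBin(con, "raw", n = n)

  if (ri(1, 4) != 348L) stopf("read_nifti: not a NIfTI-1 file: %s", path)
  skip(36)
  dim8 <- ri(8, 2)
  skip(14)
  dtcode <- ri(1, 2)
  bitpix <- ri(1, 2)
  ri(1, 2)
  pixdim <- rf(8)
  vox_offset <- rf(1)
  scl_slope <- rf(1); scl_inter <- rf(1)
  skip(2 + 2)
  rf(4)
  ri(2, 4)
  skip(80 + 24)
  ri(1, 2)
  sform_code <- ri(1, 2)
  rf(6)
  srow <- matrix(rf(12), nrow = 3, byrow = TRUE)
  skip(16 + 4)
  skip(vox_offset - 348)

  dt <- Filter(function(x) x$code == dtcode, NIFTI_DT)
  if (!length(dt)) stopf("read_nifti: unsupported datatype code %d", dtcode)
  dtname <- names(dt)[1]; dt <- dt[[1]]
  nd <- dim8[1]
  d <- dim8[2:(1 + nd)]
  n <- prod(d)
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = "little",
                  signed = dt$signed)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  affine <- diag(4)
  if (sform_code > 0) {
    affine[1:3, ] <- srow
    affine[1:3, 4] <- affine[1:3, 4] - affine[1:3, 1:3] %*% rep(1, 3)
  } else {
    affine[1, 1] <- pixdim[2]; affine[2, 2] <- pixdim[3]; affine[3, 3] <- pixdim[4]
  }
  list(data = array(vals, d), affine = affine,
       voxel_mm = pixdim[2:4], tr_s = pixdim[5], datatype = dtname)
}
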