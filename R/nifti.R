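# Minimal uncompressed NIfTI-1 volume I/O.
#
# No NIfTI reader ships with the declared dependencies, so the optional
# volume entry point carries its own single-file (.nii) reader/writer
# covering the handful of scalar datatypes regional summaries need. Scaled
# (scl_slope/scl_inter) data are unscaled on read; orientation metadata is
# ignored because callers must supply image and label volumes on the same
# grid.

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE))   # float64

#' Read an uncompressed NIfTI-1 volume
#'
#' Supports single-file `.nii` volumes with datatype uint8, int16, int32,
#' float32 or float64, either endianness. `scl_slope`/`scl_inter` scaling is
#' applied when set.
#'
#' @param path Path to a `.nii` file.
#' @return A numeric array with the dimensions recorded in the header.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1, 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    if (readBin(as.raw(rev(writeBin(sizeof_hdr, raw()))), "integer",
                size = 4, endian = "little") != 348L) {
      stop_input("'%s' is not a NIfTI-1 file (bad header size)", path)
    }
  }
  seek(con, 40)
  dims <- readBin(con, "integer", 8, 2, endian = endian)
  ndim <- dims[1]
  if (ndim < 1 || ndim > 7) stop_input("invalid NIfTI dimension count %d", ndim)
  shape <- dims[2:(1 + ndim)]
  seek(con, 70)
  datatype <- readBin(con, "integer", 1, 2, endian = endian)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop_input("unsupported NIfTI datatype code %d", datatype)
  seek(con, 112)
  scl_slope <- readBin(con, "double", 1, 4, endian = endian)
  scl_inter <- readBin(con, "double", 1, 4, endian = endian)
  seek(con, 108)
  vox_offset <- readBin(con, "double", 1, 4, endian = endian)
  seek(con, 344)
  magic <- rawToChar(readBin(con, "raw", 3))
  if (!identical(magic, "n+1")) {
    stop_input("only single-file (.nii, magic 'n+1') NIfTI volumes are supported")
  }
  seek(con, max(vox_offset, 352))
  n <- prod(shape)
  data <- readBin(con, dt$what, n, dt$size, signed = dt$signed,
                  endian = endian)
  if (length(data) != n) stop_input("truncated NIfTI data in '%s'", path)
  data <- as.numeric(data)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  array(data, dim = shape)
}

#' Write an array as an uncompressed NIfTI-1 volume
#'
#' @param x Numeric array (up to 7 dimensions).
#' @param path Output `.nii` path.
#' @param datatype `"float64"` (default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, datatype = c("float64", "float32")) {
  datatype <- match.arg(datatype)
  code <- if (datatype == "float64") 64L else 16L
  size <- if (datatype == "float64") 8L else 4L
  shape <- dim(x)
  if (is.null(shape)) shape <- length(x)
  if (length(shape) > 7) stop_input("at most 7 dimensions supported")
  dims <- integer(8)
  dims[1] <- length(shape)
  dims[seq_along(shape) + 1] <- shape
  dims[dims == 0L] <- 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, 4, endian = "little")                      # sizeof_hdr, @0
  writeBin(raw(36), con)                                         # unused, @4
  writeBin(as.integer(dims), con, 2, endian = "little")          # dim[8], @40
  writeBin(raw(14), con)                                         # intent fields, @56
  writeBin(code, con, 2, endian = "little")                      # datatype, @70
  writeBin(as.integer(size * 8), con, 2, endian = "little")      # bitpix, @72
  writeBin(raw(2), con)                                          # slice_start, @74
  writeBin(as.numeric(c(0, rep(1, 7))), con, 4, endian = "little") # pixdim, @76
  writeBin(352, con, 4, endian = "little")                       # vox_offset, @108
  writeBin(c(1, 0), con, 4, endian = "little")                   # scl_slope/inter, @112
  writeBin(raw(344 - 120), con)                                  # rest of header, @120
  writeBin(c(charToRaw("n+1"), raw(1)), con)                     # magic, @344
  writeBin(raw(4), con)                                          # extension flag, @348
  writeBin(as.numeric(x), con, size, endian = "little")          # voxels, @352
  invisible(path)
}
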