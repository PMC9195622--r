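# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# No NIfTI package is available in the target environment, so the subset of
# the format this pipeline needs is implemented here: 3D/4D volumes, the
# common datatypes, little- or big-endian files, and the TR carried in
# pixdim[4]. Orientation metadata (qform/sform) is passed through as identity;
# this package treats voxel geometry as metadata only.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`   = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`   = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16`  = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64`  = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L),
  `512` = list(what = "integer", size = 2L, signed = FALSE, bitpix = 16L)
)

#' Write a 3D or 4D array as a NIfTI-1 file
#'
#' @param data numeric or integer array with 3 or 4 dimensions.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param pixdim voxel spacings in mm, length 3.
#' @param tr repetition time in seconds, stored in `pixdim[4]`; only
#'   meaningful for 4D data.
#' @param datatype NIfTI datatype code; by default integer arrays are stored
#'   as int32 (code 8) and numeric arrays as float64 (code 64).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, pixdim = c(1, 1, 1), tr = 0,
                        datatype = NULL) {
  nd <- length(dim(data))
  if (is.null(dim(data)) || !(nd %in% c(3L, 4L)))
    stop_arg("data must be a 3D or 4D array")
  if (is.null(datatype))
    datatype <- if (is.integer(data) || isTRUE(all(data == round(data))))
      8L else 64L
  spec <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(spec)) stop_arg("unsupported NIfTI datatype code ", datatype)
  dims <- dim(data)
  dim8 <- integer(8)
  dim8[1] <- nd
  dim8[seq_len(nd) + 1L] <- dims
  dim8[dim8 == 0L] <- 1L
  pd8 <- numeric(8)
  pd8[1] <- 1
  pd8[2:4] <- pixdim
  pd8[5] <- tr

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  end <- "little"
  writeBin(348L, con, size = 4L, endian = end)
  writeBin(raw(36L), con)                                   # data_type..db_name+extents+session+regular+dim_info
  writeBin(as.integer(dim8), con, size = 2L, endian = end)  # dim[8]
  writeBin(numeric(3), con, size = 4L, endian = end)        # intent_p1..p3
  writeBin(0L, con, size = 2L, endian = end)                # intent_code
  writeBin(as.integer(datatype), con, size = 2L, endian = end)
  writeBin(as.integer(spec$bitpix), con, size = 2L, endian = end)
  writeBin(0L, con, size = 2L, endian = end)                # slice_start
  writeBin(pd8, con, size = 4L, endian = end)               # pixdim[8]
  writeBin(352, con, size = 4L, endian = end)               # vox_offset
  writeBin(c(1, 0), con, size = 4L, endian = end)           # scl_slope, scl_inter
  writeBin(0L, con, size = 2L, endian = end)                # slice_end
  writeBin(raw(1L), con)                                    # slice_code
  writeBin(as.raw(10L), con)                                # xyzt_units: mm | sec
  writeBin(numeric(4), con, size = 4L, endian = end)        # cal_max..toffset
  writeBin(integer(2), con, size = 4L, endian = end)        # glmax, glmin
  desc <- charToRaw("alffsvm")
  writeBin(c(desc, raw(80L - length(desc))), con)           # descrip
  writeBin(raw(24L), con)                                   # aux_file
  writeBin(c(0L, 2L), con, size = 2L, endian = end)         # qform, sform codes
  writeBin(numeric(6), con, size = 4L, endian = end)        # quatern + qoffset
  srow <- rbind(c(pixdim[1], 0, 0, 0), c(0, pixdim[2], 0, 0),
                c(0, 0, pixdim[3], 0))
  writeBin(as.numeric(t(srow)), con, size = 4L, endian = end)
  writeBin(raw(16L), con)                                   # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)            # magic
  writeBin(raw(4L), con)                                    # header extension flag
  if (spec$what == "integer") {
    storage.mode(data) <- "integer"
    writeBin(as.vector(data), con, size = spec$size, endian = end)
  } else {
    writeBin(as.numeric(as.vector(data)), con, size = spec$size, endian = end)
  }
  invisible(path)
}

#' Read a NIfTI-1 file written as a single .nii or .nii.gz
#'
#' @param path file path.
#' @return a list with elements `data` (array), `dim`, `pixdim` (length 3,
#'   mm), `tr` (seconds, from `pixdim[4]`), and `datatype`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop_arg("no such file: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop_arg("truncated NIfTI header in ", path)
  end <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4L, endian = end)
  if (sz != 348L) {
    end <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4L, endian = end)
    if (sz != 348L) stop_arg(path, " is not a NIfTI-1 file")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop_arg(path, ": unsupported magic '", magic, "'")
  dim8 <- readBin(hdr[41:56], "integer", n = 8L, size = 2L, endian = end)
  nd <- dim8[1]
  if (nd < 3L || nd > 4L) stop_arg("only 3D/4D NIfTI supported (got ", nd, "D)")
  dims <- dim8[seq_len(nd) + 1L]
  datatype <- readBin(hdr[71:72], "integer", size = 2L, endian = end)
  spec <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(spec)) stop_arg("unsupported NIfTI datatype code ", datatype)
  pd8 <- readBin(hdr[77:108], "double", n = 8L, size = 4L, endian = end)
  vox_offset <- readBin(hdr[109:112], "double", size = 4L, endian = end)
  scl_slope <- readBin(hdr[113:116], "double", size = 4L, endian = end)
  scl_inter <- readBin(hdr[117:120], "double", size = 4L, endian = end)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n_vox <- prod(dims)
  vals <- readBin(con, spec$what, n = n_vox, size = spec$size,
                  signed = spec$signed, endian = end)
  if (length(vals) != n_vox) stop_arg("truncated NIfTI data in ", path)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = dims), dim = dims,
       pixdim = pd8[2:4], tr = pd8[5], datatype = datatype)
}
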