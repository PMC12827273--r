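# Minimal NIfTI-1 reader/writer.
#
# The pre-installed R stack has no NIfTI package, so the package carries a
# small single-file implementation sufficient for its own volumes: .nii or
# .nii.gz, little-endian, datatypes uint8/int16/int32/float32/float64,
# 3-D or 4-D, no extensions. Byte-swapped (big-endian) files are detected
# via sizeof_hdr and read with swapped endianness.

nifti_datatypes <- data.frame(
  code = c(2L, 4L, 8L, 16L, 64L),
  what = c("integer", "integer", "integer", "double", "double"),
  size = c(1L, 2L, 4L, 4L, 8L),
  stringsAsFactors = FALSE
)

open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write an array as a NIfTI-1 volume
#'
#' @param x numeric 3-D or 4-D array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param datatype `"float32"` (default), `"float64"`, or `"int16"` /
#'   `"int32"` / `"uint8"` for label volumes.
#' @param pixdim voxel dimensions (mm / s), recycled to the array rank.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, datatype = "float32", pixdim = 1) {
  dims <- dim(x)
  if (is.null(dims) || !(length(dims) %in% c(3L, 4L))) {
    stopf("write_nifti: 'x' must be a 3-D or 4-D array")
  }
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 stopf("write_nifti: unsupported datatype '%s'", datatype))
  dt <- nifti_datatypes[nifti_datatypes$code == code, ]
  con <- open_maybe_gz(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  wd <- function(v) writeBin(as.double(v), con, size = 4L, endian = "little")
  wi(348L, 4)                               # sizeof_hdr
  writeBin(raw(36), con)                    # data_type, db_name, extents, ...
  dim8 <- c(length(dims), dims, rep(1L, 7L - length(dims)))
  wi(dim8, 2)                               # dim[8]
  wd(c(0, 0, 0))                            # intent_p1..3
  wi(c(0L, code), 2)                        # intent_code, datatype
  wi(c(dt$size * 8L, 0L), 2)                # bitpix, slice_start
  pd <- c(0, rep_len(pixdim, length(dims)), rep(1, 7 - length(dims)))
  wd(pd)                                    # pixdim[8]
  wd(352)                                   # vox_offset
  wd(c(1, 0))                               # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2), con)          # slice_end, slice_code, xyzt_units
  wd(c(0, 0, 0))                            # cal_max, cal_min, slice_duration
  wd(0)                                     # toffset
  wi(c(0L, 0L), 4)                          # glmax, glmin
  writeBin(raw(104), con)                   # descrip(80) + aux_file(24)
  wi(c(0L, 0L), 2)                          # qform_code, sform_code
  wd(rep(0, 18))                            # quatern/qoffset + srow
  writeBin(raw(16), con)                    # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL); writeBin(as.raw(c(0, 0, 0, 0, 0)), con)
  vals <- as.vector(x)
  if (dt$what == "integer") {
    writeBin(as.integer(round(vals)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return numeric array with `dim` set; voxel dimensions in attribute
#'   `pixdim`, datatype code in attribute `datatype`.
#' @export
read_nifti <- function(path) {
  con <- open_maybe_gz(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stopf("read_nifti: '%s' is not a NIfTI-1 file", path)
  rd_i <- function(off, n, size, endian) {
    readBin(hdr[(off + 1):(off + n * size)], "integer", n = n, size = size,
            endian = endian)
  }
  endian <- "little"
  if (rd_i(0, 1, 4, endian) != 348L) {
    endian <- "big"
    if (rd_i(0, 1, 4, endian) != 348L) {
      stopf("read_nifti: '%s' lacks a NIfTI-1 header", path)
    }
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    stopf("read_nifti: unsupported magic '%s'", magic)
  }
  dim8 <- rd_i(40, 8, 2, endian)
  rank <- dim8[1]
  if (!rank %in% c(3L, 4L)) stopf("read_nifti: only 3-D/4-D volumes supported")
  dims <- dim8[2:(1 + rank)]
  datatype <- rd_i(70, 1, 2, endian)
  dt <- nifti_datatypes[nifti_datatypes$code == datatype, ]
  if (!nrow(dt)) stopf("read_nifti: unsupported datatype code %d", datatype)
  pixdim <- readBin(hdr[77:108], "double", n = 8, size = 4, endian = endian)
  vox_offset <- readBin(hdr[109:112], "double", n = 1, size = 4, endian = endian)
  scl <- readBin(hdr[113:120], "double", n = 2, size = 4, endian = endian)
  skip <- max(vox_offset, 348) - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  n_vox <- prod(dims)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size, endian = endian,
                  signed = !(datatype == 2L))
  if (length(vals) < n_vox) stopf("read_nifti: truncated data in '%s'", path)
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0)) {
    vals <- vals * scl[1] + scl[2]
  }
  out <- array(vals, dim = dims)
  attr(out, "pixdim") <- pixdim[2:(1 + rank)]
  attr(out, "datatype") <- datatype
  out
}
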