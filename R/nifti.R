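# Minimal NIfTI-1 I/O. Only the subset the pipeline needs: single-frame 3D
# volumes, float32 or uint8 storage, little-endian, optional gzip (by the
# .gz suffix), spacing carried in pixdim and a diagonal sform.
# No pre-installed R package in this stack reads NIfTI, hence this shim.

NIFTI_DT_UINT8 <- 2L
NIFTI_DT_FLOAT32 <- 16L

#' Write a 3D volume as a NIfTI-1 file
#'
#' @param vol 3D numeric (or logical/integer) array.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param spacing voxel size per axis in mm (length 3).
#' @param datatype `"float32"` or `"uint8"` (use uint8 for binary masks).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, spacing = c(1, 1, 1),
                        datatype = c("float32", "uint8")) {
  stopifnot(length(dim(vol)) == 3L, length(spacing) == 3L)
  datatype <- match.arg(datatype)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  d <- dim(vol)
  code <- if (datatype == "uint8") NIFTI_DT_UINT8 else NIFTI_DT_FLOAT32
  bitpix <- if (datatype == "uint8") 8L else 32L

  wi <- function(x, size = 4L) writeBin(as.integer(x), con, size = size,
                                        endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wpad <- function(n) writeBin(raw(n), con)

  wi(348L)                                   # sizeof_hdr
  wpad(36L)                                  # data_type, db_name, extents, ...
  wi(c(3L, d, 1L, 1L, 1L, 1L), size = 2L)    # dim[8]
  wf(c(0, 0, 0))                             # intent_p1..p3
  wi(0L, 2L)                                 # intent_code
  wi(code, 2L)                               # datatype
  wi(bitpix, 2L)                             # bitpix
  wi(0L, 2L)                                 # slice_start
  wf(c(1, spacing, 1, 1, 1, 1))              # pixdim[8] (qfac = 1)
  wf(352)                                    # vox_offset
  wf(c(1, 0))                                # scl_slope, scl_inter
  wi(0L, 2L); wi(0L, 1L); wi(0L, 1L)         # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                             # cal_max, cal_min, slice_duration
  wf(0)                                      # toffset
  wi(c(0L, 0L))                              # glmax, glmin
  wpad(80L + 24L)                            # descrip, aux_file
  wi(c(0L, 1L), 2L)                          # qform_code = 0, sform_code = 1
  wf(rep(0, 6))                              # quatern b,c,d + qoffset x,y,z
  wf(c(spacing[1], 0, 0, 0))                 # srow_x
  wf(c(0, spacing[2], 0, 0))                 # srow_y
  wf(c(0, 0, spacing[3], 0))                 # srow_z
  wpad(16L)                                  # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  writeBin(raw(1L), con)
  writeBin(raw(4L), con)                     # extension flag

  vals <- as.vector(vol)
  if (datatype == "uint8") {
    writeBin(as.raw(as.integer(round(vals))), con)
  } else {
    writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file written by [write_nifti()]
#'
#' Supports 3D little-endian uint8/float32 single-file NIfTI-1.
#'
#' @param path file path (`.gz` handled transparently).
#' @return list with `vol` (3D array) and `spacing` (length-3 numeric).
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size = 4L) readBin(con, "integer", n = n, size = size,
                                       endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4L, endian = "little")
  hdr_size <- ri(1L)
  if (!identical(hdr_size, 348L)) stop("not a little-endian NIfTI-1 file: ", path)
  readBin(con, "raw", 36L)
  dims <- ri(8L, 2L)
  if (dims[1] != 3L) stop("only 3D NIfTI supported")
  d <- dims[2:4]
  rf(3L); ri(1L, 2L)
  datatype <- ri(1L, 2L)
  ri(1L, 2L); ri(1L, 2L)
  pixdim <- rf(8L)
  vox_offset <- rf(1L)
  readBin(con, "raw", 348L - 112L)           # rest of the header
  skip <- vox_offset - 348L
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(d)
  vol <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n = n, size = 1L, signed = FALSE)),
    "16" = readBin(con, "numeric", n = n, size = 4L, endian = "little"),
    stop("unsupported NIfTI datatype code: ", datatype))
  list(vol = array(vol, d), spacing = pixdim[2:4])
}
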