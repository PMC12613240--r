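# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# No NIfTI package is available in the target R stack, so the subset of the
# format this pipeline needs is implemented directly: 3D/4D volumes, little-
# or big-endian headers, datatypes uint8/int16/int32/float32/float64 with
# scl_slope/scl_inter scaling, and a diagonal RAS+ sform. Volumes written by
# this package always use float64 so that signal arrays round-trip exactly.

NIFTI_DT <- list(`2` = list(what = "integer",  size = 1L, signed = FALSE),
                 `4` = list(what = "integer",  size = 2L, signed = TRUE),
                 `8` = list(what = "integer",  size = 4L, signed = TRUE),
                 `16` = list(what = "numeric", size = 4L, signed = TRUE),
                 `64` = list(what = "numeric", size = 8L, signed = TRUE))

open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D or 4D array as a NIfTI-1 volume
#'
#' @param data numeric array (3D or 4D).
#' @param geometry `cest_geometry` describing the first three dimensions.
#' @param path output path; `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, geometry, path) {
  dims <- dim(data)
  stopifnot(length(dims) %in% c(3L, 4L))
  if (!identical(dims[1:3], as.integer(geometry$matrix_dims)))
    stop("data dimensions do not match geometry")
  con <- open_maybe_gz(path, "wb")
  on.exit(close(con))
  ndim <- length(dims)
  dim8 <- c(ndim, dims, rep(1L, 7 - ndim))
  pixdim <- c(1, geometry$voxel_size_mm, rep(1, 4))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(348L, 4)                                  # sizeof_hdr
  writeBin(raw(36), con)                       # data_type..dim_info
  wi(dim8, 2)                                  # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)                    # intent_p1..p3, intent_code
  wi(64L, 2); wi(64L, 2)                       # datatype float64, bitpix
  wi(0L, 2)                                    # slice_start
  wf(pixdim)                                   # pixdim[8]
  wf(352)                                      # vox_offset
  wf(1); wf(0)                                 # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2), con)             # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0)); wi(c(0L, 0L), 4)          # cal_max..glmin
  writeBin(raw(104), con)                      # descrip, aux_file
  wi(c(0L, 1L), 2)                             # qform_code=0, sform_code=1
  wf(rep(0, 6))                                # quatern b,c,d + qoffset x,y,z
  o <- geometry$origin_offset_mm; v <- geometry$voxel_size_mm
  wf(c(v[1], 0, 0, o[1]))                      # srow_x
  wf(c(0, v[2], 0, o[2]))                      # srow_y
  wf(c(0, 0, v[3], o[3]))                      # srow_z
  writeBin(raw(16), con)                       # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)
  writeBin(raw(4), con)                        # extension flag
  writeBin(as.numeric(data), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (numeric array) and `geometry` (`cest_geometry`).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- open_maybe_gz(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop(path, ": truncated NIfTI header")
  endian <- "little"
  rd_i <- function(off, n, size) readBin(hdr[(off + 1):(off + n * size)], "integer",
                                         n = n, size = size, endian = endian,
                                         signed = size > 1)
  rd_f <- function(off, n) readBin(hdr[(off + 1):(off + n * 4)], "numeric",
                                   n = n, size = 4L, endian = endian)
  if (rd_i(0, 1, 4) != 348L) {
    endian <- "big"
    if (rd_i(0, 1, 4) != 348L) stop(path, ": not a NIfTI-1 file")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop(path, ": unsupported NIfTI magic '", magic, "'")
  dim8 <- rd_i(40, 8, 2)
  ndim <- dim8[1]
  if (!ndim %in% c(3L, 4L)) stop(path, ": only 3D/4D volumes are supported")
  dims <- dim8[2:(1 + ndim)]
  datatype <- rd_i(70, 1, 2)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop(path, ": unsupported NIfTI datatype ", datatype)
  pixdim <- rd_f(76, 8)
  vox_offset <- rd_f(108, 1)
  scl_slope <- rd_f(112, 1); scl_inter <- rd_f(116, 1)
  sform_code <- rd_i(254, 1, 2)
  origin <- c(0, 0, 0)
  voxsz <- pixdim[2:4]
  if (sform_code > 0L) {
    srow <- rbind(rd_f(280, 4), rd_f(296, 4), rd_f(312, 4))
    origin <- srow[, 4]
    voxsz <- abs(diag(srow[, 1:3]))
    if (any(voxsz == 0)) voxsz <- pixdim[2:4]
  }
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n <- prod(dims)
  data <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(data) < n) stop(path, ": truncated NIfTI data section")
  data <- as.numeric(data)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  dim(data) <- dims
  list(data = data,
       geometry = volume_geometry(dims[1:3], voxsz, origin))
}
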