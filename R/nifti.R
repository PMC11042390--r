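# Minimal NIfTI-1 reader/writer.
#
# The analysis environment provides no R NIfTI package, so the format is
# handled directly: the fixed 348-byte header, sform/qform affines, the
# common scalar datatypes, and gzip transparently via gzfile(). This is
# plumbing, not science; only the features the pipeline needs are supported
# (3-D scalar volumes and 4-D time-series, no extensions, no shear-free
# qform writing).

NIFTI_DTYPES <- list(
  uint8   = list(code = 2L,   bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,   bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,   bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L,  bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L,  bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

nifti_open <- function(path, mode) {
  # gzfile reads plain files too, so use it for all reads; choose on write
  if (mode == "rb") gzfile(path, "rb")
  else if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
}

read_nifti_header <- function(con) {
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("file too short to be NIfTI-1")
  endian <- "little"
  sz <- readBin(hdr_raw, "integer", n = 1L, size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr_raw, "integer", n = 1L, size = 4L, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr)")
  }
  rd <- function(offset, what, n, size) {
    readBin(hdr_raw[(offset + 1L):length(hdr_raw)], what, n = n, size = size,
            endian = endian)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic)")
  list(
    endian      = endian,
    dim         = rd(40L, "integer", 8L, 2L),
    datatype    = rd(70L, "integer", 1L, 2L),
    bitpix      = rd(72L, "integer", 1L, 2L),
    pixdim      = rd(76L, "double", 8L, 4L),
    vox_offset  = rd(108L, "double", 1L, 4L),
    scl_slope   = rd(112L, "double", 1L, 4L),
    scl_inter   = rd(116L, "double", 1L, 4L),
    qform_code  = rd(252L, "integer", 1L, 2L),
    sform_code  = rd(254L, "integer", 1L, 2L),
    quatern     = rd(256L, "double", 3L, 4L),
    qoffset     = rd(268L, "double", 3L, 4L),
    srow        = matrix(rd(280L, "double", 12L, 4L), nrow = 3L, byrow = TRUE),
    magic       = magic
  )
}

nifti_affine <- function(h) {
  if (h$sform_code > 0L) {
    rbind(h$srow, c(0, 0, 0, 1))
  } else if (h$qform_code > 0L) {
    b <- h$quatern[1]; c_ <- h$quatern[2]; d <- h$quatern[3]
    a2 <- 1 - b^2 - c_^2 - d^2
    a <- sqrt(max(a2, 0))
    R <- matrix(c(
      a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d),     2 * (b * d + a * c_),
      2 * (b * c_ + a * d),   a^2 + c_^2 - b^2 - d^2,   2 * (c_ * d - a * b),
      2 * (b * d - a * c_),   2 * (c_ * d + a * b),     a^2 + d^2 - b^2 - c_^2
    ), nrow = 3L, byrow = TRUE)
    qfac <- if (h$pixdim[1] < 0) -1 else 1
    sc <- c(h$pixdim[2], h$pixdim[3], qfac * h$pixdim[4])
    aff <- diag(4)
    aff[1:3, 1:3] <- R %*% diag(sc)
    aff[1:3, 4] <- h$qoffset
    aff
  } else {
    # fall back to pixdim scaling, origin at voxel 0
    diag(c(h$pixdim[2:4], 1))
  }
}

read_nifti_array <- function(path) {
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  h <- read_nifti_header(con)
  dt <- Filter(function(d) d$code == h$datatype, NIFTI_DTYPES)
  if (length(dt) == 0L)
    stop(sprintf("unsupported NIfTI datatype code %d", h$datatype))
  dt <- dt[[1L]]
  nd <- h$dim[1]
  if (nd < 3L || nd > 4L) stop("only 3-D and 4-D NIfTI volumes are supported")
  dims <- h$dim[2:(nd + 1L)]
  n <- prod(dims)
  # skip from byte 348 to vox_offset
  skip <- as.integer(round(h$vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = h$endian)
  if (length(vals) != n) stop("truncated NIfTI data section")
  vals <- as.numeric(vals)
  if (is.finite(h$scl_slope) && h$scl_slope != 0 &&
      !(h$scl_slope == 1 && h$scl_inter == 0)) {
    vals <- vals * h$scl_slope + h$scl_inter
  }
  list(data = array(vals, dim = dims), affine = nifti_affine(h), header = h)
}

write_nifti_header <- function(con, dims, dtype, affine, endian = "little") {
  dt <- NIFTI_DTYPES[[dtype]]
  nd <- length(dims)
  dim8 <- rep(1L, 8L); dim8[1L] <- nd; dim8[1L + seq_along(dims)] <- as.integer(dims)
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  pixdim8 <- c(1, vox, if (nd >= 4L) 1 else 1, rep(0, 3))[1:8]
  w_int32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = endian)
  w_int16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = endian)
  w_float <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = endian)
  w_raw0 <- function(n) writeBin(raw(n), con)
  w_int32(348L)                       # sizeof_hdr
  w_raw0(35L)                         # data_type, db_name, extents, session_error, regular
  w_raw0(1L)                          # dim_info
  w_int16(dim8)                       # dim[8]
  w_float(c(0, 0, 0))                 # intent_p1..p3
  w_int16(0L)                         # intent_code
  w_int16(dt$code)                    # datatype
  w_int16(dt$bitpix)                  # bitpix
  w_int16(0L)                         # slice_start
  w_float(pixdim8)                    # pixdim[8]
  w_float(352)                        # vox_offset
  w_float(1)                          # scl_slope
  w_float(0)                          # scl_inter
  w_int16(0L)                         # slice_end
  w_raw0(2L)                          # slice_code, xyzt_units
  w_float(c(0, 0, 0, 0))              # cal_max, cal_min, slice_duration, toffset
  w_int32(c(0L, 0L))                  # glmax, glmin
  w_raw0(80L + 24L)                   # descrip, aux_file
  w_int16(0L)                         # qform_code
  w_int16(1L)                         # sform_code (affine stored in srow)
  w_float(c(0, 0, 0))                 # quatern b, c, d
  w_float(c(0, 0, 0))                 # qoffset
  w_float(affine[1, ])                # srow_x
  w_float(affine[2, ])                # srow_y
  w_float(affine[3, ])                # srow_z
  w_raw0(16L)                         # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  w_raw0(4L)                          # extension flag: none
}

write_nifti_array <- function(data, affine, path, dtype = "float64") {
  stopifnot(dtype %in% names(NIFTI_DTYPES))
  dt <- NIFTI_DTYPES[[dtype]]
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  write_nifti_header(con, dim(data), dtype, affine)
  vals <- as.vector(data)
  if (dt$what == "integer") {
    vals[!is.finite(vals)] <- 0
    writeBin(as.integer(round(vals)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads a 3-D scalar volume (.nii or .nii.gz). The affine is taken from the
#' sform if set, else the qform, else pixdim scaling. Non-finite voxels are
#' excluded from the analysis mask; an all-finite volume gets an all-TRUE
#' mask.
#'
#' @param path path to a NIfTI-1 file.
#' @param expected_grid optional [brain_grid()]; a mismatch (shape or affine
#'   beyond 1e-6) raises an error, signalling that resampling is needed
#'   upstream (never performed here).
#' @return A [brain_volume()].
#' @export
read_volume <- function(path, expected_grid = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  x <- read_nifti_array(path)
  if (length(dim(x$data)) == 4L) {
    if (dim(x$data)[4] == 1L) x$data <- array(x$data, dim = dim(x$data)[1:3])
    else stop("4-D file: use read_timeseries() for time-series volumes")
  }
  grid <- brain_grid(dim(x$data), x$affine)
  if (!is.null(expected_grid)) stop_if_grid_mismatch(grid, expected_grid, "file and expected grid")
  brain_volume(grid, x$data)
}

#' Write a volume as NIfTI-1
#'
#' Out-of-mask voxels are written as stored (NA becomes NaN in float output).
#'
#' @param vol a [brain_volume()].
#' @param path output path (.nii, or .nii.gz for gzip).
#' @param dtype one of "float64", "float32", "int16", "int32", "uint8".
#' @export
write_volume <- function(vol, path, dtype = "float64") {
  stopifnot(inherits(vol, "brain_volume"))
  write_nifti_array(vol$data, vol$grid$affine, path, dtype)
}

#' Read a 4-D NIfTI time-series
#'
#' @param path path to a 4-D NIfTI-1 file (x, y, z, time).
#' @return list with `grid` ([brain_grid()]) and `data` (4-D array).
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  x <- read_nifti_array(path)
  if (length(dim(x$data)) != 4L) stop("expected a 4-D time-series volume")
  list(grid = brain_grid(dim(x$data)[1:3], x$affine), data = x$data)
}

#' Write a 4-D time-series as NIfTI-1
#'
#' @param data 4-D array (x, y, z, time).
#' @param grid a [brain_grid()] for the spatial axes.
#' @param path output path.
#' @param dtype storage type, default "float32".
#' @export
write_timeseries <- function(data, grid, path, dtype = "float32") {
  stopifnot(length(dim(data)) == 4L, all(dim(data)[1:3] == grid$shape))
  write_nifti_array(data, grid$affine, path, dtype)
}
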