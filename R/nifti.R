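# Minimal NIfTI-1 I/O.
#
# The package ships its own compact NIfTI-1 codec (no NIfTI package is a
# declared dependency): 3D images, the common datatypes, optional gzip, and
# the sform for spatial metadata. NIfTI-1 coordinates are voxel-center based;
# spacing comes from pixdim, origin from the sform translation column.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

nifti_connection <- function(path, mode) {
  # gzfile transparently reads uncompressed files too
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' Reads a 3D NIfTI-1 image (`.nii` or `.nii.gz`), applying any intensity
#' scaling stored in the header. Trailing singleton dimensions are dropped;
#' genuinely 4D images are rejected.
#'
#' @param path path to a NIfTI-1 file.
#' @return a [volume_image].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stopf("cannot read NIfTI volume: no such file '%s'", path)
  }
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stopf("corrupt NIfTI file '%s': short header", path)

  parse_hdr <- function(raw, endian) {
    rc <- rawConnection(raw)
    on.exit(close(rc))
    rd <- function(what, n, size, signed = TRUE) {
      readBin(rc, what, n = n, size = size, endian = endian, signed = signed)
    }
    h <- list()
    h$sizeof_hdr <- rd("integer", 1L, 4L)
    invisible(rd("raw", 36L, 1L))                       # data_type..dim_info
    h$dim <- rd("integer", 8L, 2L)
    invisible(rd("double", 3L, 4L)); invisible(rd("integer", 1L, 2L))
    h$datatype <- rd("integer", 1L, 2L)
    h$bitpix <- rd("integer", 1L, 2L)
    invisible(rd("integer", 1L, 2L))                    # slice_start
    h$pixdim <- rd("double", 8L, 4L)
    h$vox_offset <- rd("double", 1L, 4L)
    h$scl_slope <- rd("double", 1L, 4L)
    h$scl_inter <- rd("double", 1L, 4L)
    invisible(rd("raw", 28L, 1L))                       # slice_end..glmin
    invisible(rd("raw", 104L, 1L))                      # descrip + aux_file
    h$qform_code <- rd("integer", 1L, 2L)
    h$sform_code <- rd("integer", 1L, 2L)
    h$quatern <- rd("double", 3L, 4L)
    h$qoffset <- rd("double", 3L, 4L)
    h$srow_x <- rd("double", 4L, 4L)
    h$srow_y <- rd("double", 4L, 4L)
    h$srow_z <- rd("double", 4L, 4L)
    invisible(rd("raw", 16L, 1L))
    h$magic <- rawToChar(rd("raw", 4L, 1L)[1:3])
    h
  }

  hdr <- parse_hdr(hdr_raw, "little")
  endian <- "little"
  if (hdr$sizeof_hdr != 348L) {
    hdr <- parse_hdr(hdr_raw, "big")
    endian <- "big"
    if (hdr$sizeof_hdr != 348L) stopf("'%s' is not a NIfTI-1 file", path)
  }
  if (!hdr$magic %in% c("n+1", "ni1")) {
    stopf("'%s' is not a NIfTI-1 file (bad magic '%s')", path, hdr$magic)
  }
  ndim <- hdr$dim[1]
  dims <- hdr$dim[seq(2, length.out = max(ndim, 0L))]
  if (ndim < 3L || any(dims[-(1:3)] > 1L)) {
    stopf("'%s' is %dD with extents [%s]; only 3D volumes are supported",
          path, ndim, paste(dims, collapse = "x"))
  }
  dims3 <- dims[1:3]
  dt <- NIFTI_DTYPES[[as.character(hdr$datatype)]]
  if (is.null(dt)) stopf("unsupported NIfTI datatype code %d", hdr$datatype)

  skip <- hdr$vox_offset - 348
  if (skip > 0) invisible(readBin(con, "raw", n = as.integer(skip)))
  n <- prod(dims3)
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(vals) < n) stopf("corrupt NIfTI file '%s': truncated data", path)
  vals <- as.numeric(vals)
  if (is.finite(hdr$scl_slope) && hdr$scl_slope != 0 &&
      !(hdr$scl_slope == 1 && hdr$scl_inter == 0)) {
    vals <- vals * hdr$scl_slope + hdr$scl_inter
  }
  spacing <- abs(hdr$pixdim[2:4])
  origin <- if (hdr$sform_code > 0L) {
    c(hdr$srow_x[4], hdr$srow_y[4], hdr$srow_z[4])
  } else {
    hdr$qoffset
  }
  volume_image(array(vals, dim = dims3), spacing = spacing, origin = origin)
}

# Serialize a header + data blob; dims beyond 3 only used internally/tests.
nifti_write_raw <- function(data, dims, spacing, origin, path) {
  ndim <- length(dims)
  dimfield <- rep(1L, 8L); dimfield[1] <- ndim
  dimfield[seq(2, 1 + ndim)] <- as.integer(dims)
  pixdim <- rep(1, 8); pixdim[2:4] <- spacing

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  w(348L, 4L)
  w(raw(36L), 1L)                                   # data_type..dim_info
  w(dimfield, 2L)
  w(c(0, 0, 0), 4L); w(0L, 2L)                      # intent
  w(16L, 2L); w(32L, 2L); w(0L, 2L)                 # float32, bitpix, slice_start
  w(pixdim, 4L)
  w(352, 4L)                                        # vox_offset
  w(1, 4L); w(0, 4L)                                # scl_slope/inter
  w(0L, 2L); w(raw(2L), 1L)                         # slice_end, slice_code+xyzt
  w(c(0, 0, 0, 0), 4L)                              # cal_max..toffset
  w(c(0L, 0L), 4L)                                  # glmax, glmin
  w(raw(104L), 1L)                                  # descrip + aux_file
  w(0L, 2L); w(1L, 2L)                              # qform_code=0, sform_code=1
  w(c(0, 0, 0), 4L)                                 # quatern
  w(origin, 4L)                                     # qoffset mirrors sform
  w(c(spacing[1], 0, 0, origin[1]), 4L)
  w(c(0, spacing[2], 0, origin[2]), 4L)
  w(c(0, 0, spacing[3], origin[3]), 4L)
  w(raw(16L), 1L)
  writeBin(charToRaw("n+1"), con); w(raw(1L), 1L)
  w(raw(4L), 1L)                                    # extension flag
  w(as.numeric(data), 4L)                           # float32 payload
  invisible(path)
}

#' Write a volume as NIfTI-1
#'
#' Stores the image as float32 with diagonal sform carrying spacing and
#' origin. Gzip compression is chosen from the file extension.
#'
#' @param vol a [volume_image].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path) {
  assert_volume(vol)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  nifti_write_raw(vol$data, dim(vol$data), vol$spacing, vol$origin, path)
  invisible(path)
}
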