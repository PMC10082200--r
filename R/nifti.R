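# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# The pre-installed R stack has no NIfTI package, so the format is handled
# here directly: a 348-byte header, a 4-byte extension flag, then the voxel
# block in x-fastest (column-major) order.  Only the features this package
# needs are supported: 2D/3D scalar images, datatypes uint8 / int16 / int32 /
# float32 / float64, scl_slope/scl_inter rescaling, both endiannesses.
# Orientation matrices are ignored beyond the axis reordering documented in
# read_volume(); pixdim carries the voxel spacing.

NIFTI_DT <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE),
  `4`  = list(what = "integer", size = 2, signed = TRUE),
  `8`  = list(what = "integer", size = 4, signed = TRUE),
  `16` = list(what = "double",  size = 4, signed = TRUE),
  `64` = list(what = "double",  size = 8, signed = TRUE)
)

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

# Returns list(data = array (x,y,z order as stored), spacing = pixdim per
# stored axis, dim = integer dims).
nifti_read_raw <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (!identical(sizeof_hdr, 348L)) {
    endian <- "big"                      # retry with swapped byte order
    close(con)
    on.exit()
    con <- nifti_open(path, "rb")
    on.exit(close(con))
    sizeof_hdr <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (!identical(sizeof_hdr, 348L))
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  readBin(con, "raw", 36)                                   # unused header
  dims <- readBin(con, "integer", 8, size = 2, endian = endian)
  readBin(con, "raw", 14)                                   # intent fields
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "integer", 1, size = 2, endian = endian)     # bitpix
  readBin(con, "integer", 1, size = 2, endian = endian)     # slice_start
  pixdim <- readBin(con, "double", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "double", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "double", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "double", 1, size = 4, endian = endian)
  # skip to magic at byte 344: consumed so far = 4+36+16+14+2+2+2+32+4+4+4=120
  readBin(con, "raw", 344 - 120)
  magic <- rawToChar(readBin(con, "raw", 4))
  if (!startsWith(magic, "n+1") && !startsWith(magic, "ni1"))
    stop("not a NIfTI-1 file (bad magic): ", path)

  nd <- dims[1]
  if (nd < 2) stop("NIfTI image must be at least 2D: ", path)
  shape <- dims[2:(nd + 1)]
  shape <- shape[shape > 0]
  extra <- shape[-(1:min(3, length(shape)))]
  if (length(extra) && any(extra != 1L))
    stop("only scalar 2D/3D NIfTI images are supported (got dims ",
         paste(shape, collapse = "x"), "): ", path)
  shape <- shape[1:min(3, length(shape))]

  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)

  # seek within gz streams is unreliable; read forward instead
  already <- 348L
  skip <- as.integer(round(vox_offset)) - already
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(shape)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) != n) stop("truncated NIfTI voxel block: ", path)
  vals <- as.double(vals)
  if (!is.na(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = shape),
       spacing = pixdim[seq_along(shape) + 1],
       dim = shape)
}

# arr: array in on-disk (x, y, z) order; spacing per stored axis.
# datatype: "uint8" or "float32".
nifti_write_raw <- function(arr, path, spacing = NULL, datatype = "float32") {
  shape <- dim(arr)
  if (is.null(shape)) shape <- length(arr)
  nd <- length(shape)
  if (nd < 2 || nd > 3) stop("only 2D/3D NIfTI output is supported")
  if (is.null(spacing)) spacing <- rep(1, nd)
  dtcode <- switch(datatype, uint8 = 2L, int16 = 4L, float32 = 16L,
                   float64 = 64L,
                   stop("unsupported output datatype: ", datatype))
  bitpix <- switch(datatype, uint8 = 8L, int16 = 16L, float32 = 32L,
                   float64 = 64L)
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)                      # sizeof_hdr
  writeBin(raw(36), con)
  dims <- integer(8)
  dims[1] <- nd
  dims[2:(nd + 1)] <- shape
  if (nd < 7) dims[(nd + 2):8] <- 1L
  writeBin(as.integer(dims), con, size = 2)
  writeBin(raw(14), con)
  writeBin(dtcode, con, size = 2)                    # datatype
  writeBin(bitpix, con, size = 2)                    # bitpix
  writeBin(0L, con, size = 2)                        # slice_start
  pixdim <- c(1, spacing, rep(1, 7 - nd))
  writeBin(as.double(pixdim), con, size = 4)
  writeBin(352, con, size = 4)                       # vox_offset
  writeBin(1, con, size = 4)                         # scl_slope
  writeBin(0, con, size = 4)                         # scl_inter
  # pad up to the magic field at byte 344; bytes written so far: 120
  writeBin(raw(344 - 120), con)
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)      # magic
  writeBin(raw(4), con)                              # extension flag
  vals <- as.vector(arr)
  if (datatype %in% c("uint8", "int16"))
    writeBin(as.integer(round(vals)), con, size = bitpix / 8)
  else
    writeBin(as.double(vals), con, size = bitpix / 8)
  invisible(path)
}
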