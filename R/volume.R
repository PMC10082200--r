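# Volumes, masks and the coordinate convention.
#
# Every 3D grid in this package is indexed (z, y, x): z = axial slice index,
# y = in-slice row, x = in-slice column.  All public coordinates (sample
# points, ROI boxes, flag positions) are 0-based with half-open ranges;
# conversion to R's 1-based arrays happens at the array-access boundary.

#' Construct a CT volume object
#'
#' @param data 3D numeric array indexed `(z, y, x)`.
#' @param spacing numeric length-3 voxel size in mm per `(z, y, x)` axis.
#' @param normalized logical; `TRUE` once intensities are windowed to
#'   `[0, 1]` (see [normalize_window()]), `FALSE` for raw HU.
#' @return object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), normalized = FALSE) {
  if (length(dim(data)) != 3) stop("volume data must be a 3D array")
  if (any(dim(data) < 1)) stop("volume dimensions must be positive")
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers")
  structure(list(data = data, spacing = as.numeric(spacing),
                 normalized = isTRUE(normalized)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume %d x %d x %d (z,y,x), spacing %s mm, %s>\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "x"),
              if (x$normalized) "normalized [0,1]" else "raw HU"))
  invisible(x)
}

#' Construct a binary organ mask
#'
#' @param data logical array (2D slice or 3D volume), `(z, y, x)` ordering.
#' @param label organ tag: one of `"kidney_left"`, `"kidney_right"`,
#'   `"spleen"`, `"background"`.
#' @return object of class `ct_mask`.
#' @export
ct_mask <- function(data, label = "background") {
  label <- match.arg(label,
                     c("kidney_left", "kidney_right", "spleen", "background"))
  if (is.null(dim(data))) stop("mask data must be a 2D or 3D array")
  storage.mode(data) <- "logical"
  structure(list(data = data, label = label), class = "ct_mask")
}

#' @export
print.ct_mask <- function(x, ...) {
  cat(sprintf("<ct_mask '%s' %s, %d voxels set>\n", x$label,
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

# internal: accept a ct_mask or a bare logical array
mask_data <- function(m) {
  if (inherits(m, "ct_mask")) m$data else {
    storage.mode(m) <- "logical"
    m
  }
}

#' Read a CT volume or mask from a NIfTI-1 file
#'
#' The on-disk x-fastest layout is transposed so that in R the array is
#' indexed `(z, y, x)`; voxel spacing is taken from `pixdim`.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param as_mask logical; return a [ct_mask()] (data `> 0`) instead of a
#'   volume.
#' @param label organ tag when `as_mask = TRUE`.
#' @return a `ct_volume` (or `ct_mask`).
#' @export
read_volume <- function(path, as_mask = FALSE, label = "background") {
  raw <- nifti_read_raw(path)
  if (length(raw$dim) != 3)
    stop("expected a 3D NIfTI image, got ", length(raw$dim), "D: ", path)
  dat <- aperm(raw$data, c(3, 2, 1))        # (x,y,z) -> (z,y,x)
  spacing <- rev(raw$spacing)
  if (as_mask) ct_mask(dat > 0, label)
  else ct_volume(dat, spacing,
                 normalized = min(dat) >= 0 && max(dat) <= 1)
}

#' Write a volume or mask to a NIfTI-1 file
#'
#' Masks are written as uint8 0/1, volumes as float32.  Round trips through
#' [read_volume()] are exact for masks.
#'
#' @param vol a `ct_volume` or `ct_mask` (3D).
#' @param path output `.nii` or `.nii.gz` path.
#' @param spacing spacing override (z, y, x), mm.
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path, spacing = NULL) {
  if (inherits(vol, "ct_mask")) {
    dat <- vol$data * 1L
    dtype <- "uint8"
    if (is.null(spacing)) spacing <- c(1, 1, 1)
  } else if (inherits(vol, "ct_volume")) {
    dat <- vol$data
    dtype <- "float32"
    if (is.null(spacing)) spacing <- vol$spacing
  } else stop("vol must be a ct_volume or ct_mask")
  if (length(dim(dat)) != 3) stop("only 3D images can be written")
  nifti_write_raw(aperm(dat, c(3, 2, 1)), path, spacing = rev(spacing),
                  datatype = dtype)
  invisible(path)
}

#' Window CT intensities to the unit interval
#'
#' Linear window: `clip((v - low) / (high - low), 0, 1)`.  Monotone and
#' idempotent on already-windowed data with the `(0, 1)` window.  The default
#' window is a soft-tissue display window; synthetic phantoms are generated
#' already normalized.
#'
#' @param vol `ct_volume`, or a bare numeric array/matrix.
#' @param low,high window bounds in HU, `low < high`.
#' @return same type as the input, values in `[0, 1]`.
#' @export
normalize_window <- function(vol, low = -135, high = 215) {
  if (!is.numeric(low) || !is.numeric(high) || !(low < high))
    stop("window requires low < high")
  f <- function(v) pmin(pmax((v - low) / (high - low), 0), 1)
  if (inherits(vol, "ct_volume")) {
    out <- vol
    out$data[] <- f(vol$data)
    out$normalized <- TRUE
    out
  } else {
    v <- vol
    v[] <- f(vol)
    v
  }
}

# internal 1D linear resampling of the first array dimension to `target`
# samples; endpoints map to endpoints.
resample_first_dim <- function(arr, target) {
  d <- dim(arr)
  n <- d[1]
  if (target == n) return(arr)
  pos <- if (target == 1) (n - 1) / 2 else (0:(target - 1)) * (n - 1) / (target - 1)
  lo <- pmin(floor(pos), n - 1)
  hi <- pmin(lo + 1, n - 1)
  fr <- pos - lo
  out <- array(0, dim = c(target, d[-1]))
  # flatten trailing dims for slice arithmetic
  m <- prod(d[-1])
  a <- matrix(arr, nrow = n, ncol = m)
  o <- (1 - fr) * a[lo + 1, , drop = FALSE] + fr * a[hi + 1, , drop = FALSE]
  out[] <- o
  out
}

#' Resample a volume (or projection image) to a fixed slice count
#'
#' Linear interpolation along z only; in-slice dimensions are untouched.
#' Used to bring every sagittal/coronal projection to the 43-row input the
#' per-axis classifiers expect.
#'
#' @param vol `ct_volume`, or a matrix whose rows are z.
#' @param target_z desired number of slices (rows), default 43.
#' @return same type as the input with `target_z` slices.
#' @export
resample_depth <- function(vol, target_z = 43) {
  if (!is.numeric(target_z) || target_z < 1) stop("target_z must be >= 1")
  target_z <- as.integer(target_z)
  if (inherits(vol, "ct_volume")) {
    if (dim(vol$data)[1] < 2) stop("volume must have at least 2 slices")
    if (dim(vol$data)[1] == target_z) return(vol)
    out <- vol
    sp <- vol$spacing
    sp[1] <- sp[1] * (dim(vol$data)[1] - 1) / max(target_z - 1, 1)
    out$spacing <- sp
    out$data <- resample_first_dim(vol$data, target_z)
    out
  } else {
    if (nrow(vol) < 2) stop("image must have at least 2 rows")
    resample_first_dim(vol, target_z)
  }
}

#' Crop a 2D slice to its left or right half
#'
#' Columns `[0, W/2)` for `"left"`, `[W/2, W)` for `"right"` (0-based,
#' half-open).  `"full"` returns the input unchanged.  Used because only one
#' kidney is analyzed at a time, so coronal projections are halved.
#'
#' @param image 2D matrix.
#' @param side `"left"`, `"right"` or `"full"`.
#' @return the cropped matrix.
#' @export
crop_half <- function(image, side = c("left", "right", "full")) {
  side <- match.arg(side)
  if (side == "full") return(image)
  w <- ncol(image)
  if (w %% 2 != 0) stop("image width must be even to crop in half")
  if (side == "left") image[, 1:(w / 2), drop = FALSE]
  else image[, (w / 2 + 1):w, drop = FALSE]
}
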