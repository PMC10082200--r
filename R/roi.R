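# ROI search: scan each axis with its classifier, intersect the per-axis
# decisions into a positive point grid, merge/refine in-plane, and bound the
# z extent.  Because each projection image depends on exactly one coordinate,
# scanning an axis once and combining flag vectors is an exact refactoring of
# scanning every 3D grid point with per-line exclusion: a negative line
# decision excludes the whole plane of points at once.

#' ROI search configuration
#'
#' @param scan_step in-plane scan pitch in px (default 10).
#' @param merge_distance distance at which neighboring positive grid points
#'   are connected (default 10; must be >= `scan_step`).
#' @param dilate_size square structuring element size for the final mask
#'   dilation (default 30).
#' @param side image half holding the organ (`"left"`, `"right"`, `"full"`).
#' @param z_step stride over axial slices for the Z classifier (default 1:
#'   the in-plane scan step is a 2D optimization; slices are few and each
#'   gets its own decision).
#' @param z_pad slices of padding added to the detected z run (default 2:
#'   the axial classifier cannot flag boundary slices whose organ
#'   cross-section shrinks toward zero, so the run systematically
#'   under-reaches by a slice or two at each end).
#' @param z_gap bridge false-negative gaps of up to this many consecutive
#'   slices between positive axial decisions before extracting the run
#'   (default 3) — the z analog of the in-plane point merging: isolated
#'   misses inside the organ must not split its extent in two.
#' @return object of class `search_config`.
#' @export
search_config <- function(scan_step = 10, merge_distance = 10,
                          dilate_size = 30, side = c("left", "right", "full"),
                          z_step = 1, z_pad = 2, z_gap = 3) {
  side <- match.arg(side)
  stopifnot(scan_step >= 1, merge_distance >= scan_step, dilate_size >= 1,
            z_step >= 1, z_pad >= 0, z_gap >= 0)
  structure(list(scan_step = as.integer(scan_step),
                 merge_distance = as.integer(merge_distance),
                 dilate_size = as.integer(dilate_size), side = side,
                 z_step = as.integer(z_step), z_pad = as.integer(z_pad),
                 z_gap = as.integer(z_gap)),
            class = "search_config")
}

#' Axis-aligned 3D ROI box (half-open, 0-based voxel coordinates)
#'
#' @param x0,x1,y0,y1,z0,z1 bounds with `*0 < *1`.
#' @export
roi_box <- function(x0, x1, y0, y1, z0, z1) {
  b <- list(x0 = as.integer(x0), x1 = as.integer(x1),
            y0 = as.integer(y0), y1 = as.integer(y1),
            z0 = as.integer(z0), z1 = as.integer(z1))
  if (b$x0 >= b$x1 || b$y0 >= b$y1 || b$z0 >= b$z1)
    stop("roi_box requires x0<x1, y0<y1, z0<z1")
  if (min(b$x0, b$y0, b$z0) < 0)
    stop("roi_box bounds must be non-negative")
  structure(b, class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box z[%d,%d) y[%d,%d) x[%d,%d)>\n",
              x$z0, x$z1, x$y0, x$y1, x$x0, x$x1))
  invisible(x)
}

#' Fraction of reference voxels inside an ROI box
#'
#' @param roi a [roi_box()].
#' @param mask 3D `ct_mask` or logical array.
#' @return fraction in `[0, 1]` (1 = complete containment).
#' @export
roi_coverage <- function(roi, mask) {
  m <- mask_data(mask)
  tot <- sum(m)
  if (tot == 0) return(NA_real_)
  inside <- m[(roi$z0 + 1):roi$z1, (roi$y0 + 1):roi$y1,
              (roi$x0 + 1):roi$x1, drop = FALSE]
  sum(inside) / tot
}

#' Classify the scan lines of one axis
#'
#' Extracts the projection image at coordinates `0, step, 2*step, ...`
#' (restricted to the organ's image half for the X and Y axes when
#' `cfg$side != "full"`) and records the classifier's organ/background
#' decision.  A negative decision excludes every 3D point on that line.
#'
#' @param vol normalized `ct_volume`.
#' @param axis `"X"`, `"Y"` or `"Z"`.
#' @param net the matching `axis_classifier`.
#' @param cfg a [search_config()].
#' @param target_z projection row count (default 43).
#' @return object of class `axis_flags`: list with `axis`, `coords`
#'   (0-based), `flags` (logical), `step`.
#' @export
classify_axis_lines <- function(vol, axis, net, cfg = search_config(),
                                target_z = 43) {
  if (!axis %in% c("X", "Y", "Z")) stop("axis must be X, Y or Z")
  if (!is.null(net$axis) && net$axis != axis)
    stop("classifier for axis ", net$axis, " used on axis ", axis)
  d <- dim(vol$data)
  coords <- switch(axis,
    X = {
      xr <- switch(cfg$side, left = c(0, d[3] / 2), right = c(d[3] / 2, d[3]),
                   full = c(0, d[3]))
      seq(xr[1], xr[2] - 1, by = cfg$scan_step)
    },
    Y = seq(0, d[2] - 1, by = cfg$scan_step),
    Z = seq(0, d[1] - 1, by = cfg$z_step))
  imgs <- switch(axis,
    X = vapply(coords, function(x)
      resample_depth(vol$data[, , x + 1], target_z),
      matrix(0, target_z, d[2])),
    Y = vapply(coords, function(y)
      resample_depth(crop_half(vol$data[, y + 1, ], cfg$side), target_z),
      matrix(0, target_z,
             if (cfg$side == "full") d[3] else d[3] / 2)),
    Z = vapply(coords, function(z) vol$data[z + 1, , ],
               matrix(0, d[2], d[3])))
  pred <- predict_axis(net, imgs)
  structure(list(axis = axis, coords = as.integer(coords),
                 flags = pred$label == "organ",
                 step = if (axis == "Z") cfg$z_step else cfg$scan_step),
            class = "axis_flags")
}

#' Intersect per-axis flags into the positive 3D point grid
#'
#' A grid point is positive iff all three of its lines were classified as
#' organ — exactly the agreement rule, and provably equal to brute-force
#' triple classification of every grid point.
#'
#' @param xflags,yflags,zflags `axis_flags` from one volume.
#' @return data.frame of 0-based positive points `x`, `y`, `z`.
#' @export
positive_grid <- function(xflags, yflags, zflags) {
  xs <- xflags$coords[xflags$flags]
  ys <- yflags$coords[yflags$flags]
  zs <- zflags$coords[zflags$flags]
  if (!length(xs) || !length(ys) || !length(zs))
    return(data.frame(x = integer(0), y = integer(0), z = integer(0)))
  g <- expand.grid(x = xs, y = ys, z = zs)
  g[order(g$z, g$y, g$x), , drop = FALSE]
}

#' Merge positive grid points on one axial plane into a 2D mask
#'
#' Sets each point's pixel and rasterizes straight axis-aligned segments
#' between positives that are grid neighbors at `merge_distance`; isolated
#' points stay single pixels.
#'
#' @param points data.frame with 0-based `y`, `x` (and optionally `z`).
#' @param cfg a [search_config()].
#' @param dim image size `c(rows, cols)`.
#' @return logical matrix.
#' @export
merge_points <- function(points, cfg = search_config(), dim = c(512, 512)) {
  m <- matrix(FALSE, dim[1], dim[2])
  if (!nrow(points)) return(m)
  m[cbind(points$y + 1, points$x + 1)] <- TRUE
  key <- paste(points$y, points$x)
  md <- cfg$merge_distance
  for (i in seq_len(nrow(points))) {
    y <- points$y[i]; x <- points$x[i]
    if (paste(y, x + md) %in% key) m[y + 1, (x + 1):(x + 1 + md)] <- TRUE
    if (paste(y + md, x) %in% key) m[(y + 1):(y + 1 + md), x + 1] <- TRUE
  }
  m
}

#' Refine a merged point mask
#'
#' Keeps the largest 8-connected component (discarding stray misclassified
#' points), then dilates with a centered `dilate_size` square, clipped to
#' the image.
#'
#' @param mask logical matrix.
#' @param cfg a [search_config()].
#' @return logical matrix.
#' @export
refine_mask <- function(mask, cfg = search_config()) {
  if (!any(mask)) {
    warning("refine_mask: empty input mask")
    return(mask)
  }
  dilate_square(largest_component(mask, 8), cfg$dilate_size)
}

#' Locate the 3D ROI cube of an organ
#'
#' Scans the three axes, intersects the decisions, merges and refines the
#' in-plane positive grid (identical across z, so computed once), and bounds
#' z by the longest contiguous run of positive axial slices padded by
#' `cfg$z_pad` slices on each side.
#'
#' @param vol normalized `ct_volume`.
#' @param nets named list with trained classifiers `X`, `Y`, `Z`.
#' @param cfg a [search_config()].
#' @param target_z projection row count.
#' @param organ organ label, used in the detection-failure message.
#' @return a [roi_box()].
#' @export
find_roi <- function(vol, nets, cfg = search_config(), target_z = 43,
                     organ = NULL) {
  d <- dim(vol$data)
  xf <- classify_axis_lines(vol, "X", nets$X, cfg, target_z)
  yf <- classify_axis_lines(vol, "Y", nets$Y, cfg, target_z)
  zf <- classify_axis_lines(vol, "Z", nets$Z, cfg, target_z)
  if (!any(xf$flags) || !any(yf$flags) || !any(zf$flags))
    stop("ROI detection failed",
         if (!is.null(organ)) paste0(" for '", organ, "'") else "",
         ": no positive ",
         paste(c("X", "Y", "Z")[!c(any(xf$flags), any(yf$flags), any(zf$flags))],
               collapse = "/"),
         " lines found")
  plane <- expand.grid(x = xf$coords[xf$flags], y = yf$coords[yf$flags])
  merged <- merge_points(plane, cfg, dim = d[2:3])
  refined <- refine_mask(merged, cfg)
  bb <- mask_bbox(refined)
  # bridge short false-negative gaps, then take the longest positive run
  flags <- zf$flags
  r0 <- rle(flags)
  if (length(r0$lengths) > 2) {
    gap_ok <- !r0$values & r0$lengths <= max(0, cfg$z_gap %||% 0)
    interior <- seq_along(r0$values) > 1 & seq_along(r0$values) < length(r0$values)
    r0$values[gap_ok & interior] <- TRUE
    flags <- inverse.rle(r0)
  }
  zf$flags <- flags
  r <- rle(zf$flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  zlo <- zf$coords[starts[best]]
  zhi <- zf$coords[ends[best]]
  roi_box(x0 = bb$c0, x1 = bb$c1 + 1,
          y0 = bb$r0, y1 = bb$r1 + 1,
          z0 = max(0, zlo - cfg$z_pad),
          z1 = min(d[1], zhi + cfg$z_pad + 1))
}

#' Serialize / read an ROI box as JSON
#'
#' @param roi a [roi_box()].
#' @param path output path.
#' @param extra named list of extra fields (e.g. config hash).
#' @export
write_roi <- function(roi, path, extra = list()) {
  jsonlite::write_json(c(unclass(roi), extra), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  j <- jsonlite::read_json(path)
  roi_box(j$x0, j$x1, j$y0, j$y1, j$z0, j$z1)
}
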