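# Training-set construction: organ-class (OC) and background-class (BC)
# points from expert 2D masks, and the three projection images attached to
# every 3D point.  All point coordinates are 0-based.

#' Sampling configuration
#'
#' @param grid_spacing point grid pitch in px (default 50).
#' @param dilation_radius radius of the Euclidean disk the mask is dilated
#'   by before BC point generation (default 60 px).
#' @param strip_pad enlargement of the excluded horizontal/vertical strips
#'   beyond the mask bounding box, px per direction (default 20).
#' @param slice_stride take every k-th annotated axial slice when building
#'   the X/Y training sets (default 1 = every slice).
#' @param z_stride stride over axial slices for the Z (axial) training set.
#' @param z_margin when subsampling with `z_stride`, additionally keep every
#'   slice within this distance of the organ's z extremes (default 3).  The
#'   organ fills most of the depth range, so the strided backbone alone
#'   under-represents the boundary slices that define the axial decision.
#' @param bc_max cap on BC points kept per slice (seeded subsample,
#'   default `Inf` = keep all).  A runtime control, not part of the method.
#' @param z_cases number of cohort cases feeding the axial (Z) training set
#'   (default `Inf` = all).  Axial-set diversity is dominated by slice
#'   position rather than anatomy, and axial images are by far the most
#'   expensive to train on; a runtime control.
#' @return object of class `sampling_config`.
#' @export
sampling_config <- function(grid_spacing = 50, dilation_radius = 60,
                            strip_pad = 20, slice_stride = 1, z_stride = 1,
                            z_margin = 3, bc_max = Inf, z_cases = Inf) {
  stopifnot(grid_spacing >= 1, dilation_radius > 0, strip_pad >= 0,
            slice_stride >= 1, z_stride >= 1, z_margin >= 0, bc_max >= 1,
            z_cases >= 1)
  structure(list(grid_spacing = grid_spacing,
                 dilation_radius = dilation_radius,
                 strip_pad = strip_pad,
                 slice_stride = as.integer(slice_stride),
                 z_stride = as.integer(z_stride),
                 z_margin = as.integer(z_margin),
                 bc_max = bc_max,
                 z_cases = z_cases),
            class = "sampling_config")
}

# 0-based bounding box of a logical matrix: list(r0, r1, c0, c1), inclusive.
mask_bbox <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (!length(rows)) return(NULL)
  list(r0 = min(rows) - 1L, r1 = max(rows) - 1L,
       c0 = min(cols) - 1L, c1 = max(cols) - 1L)
}

#' Organ-class sample points of one annotated slice
#'
#' Lays a grid with pitch `grid_spacing` anchored at the top-left corner of
#' the mask bounding box and keeps the grid points that fall inside the
#' expert mask.
#'
#' @param mask 2D `ct_mask` or logical matrix.
#' @param cfg a [sampling_config()].
#' @return data.frame with 0-based columns `y`, `x` (empty for empty masks).
#' @export
organ_points <- function(mask, cfg = sampling_config()) {
  m <- mask_data(mask)
  if (length(dim(m)) != 2) stop("organ_points expects a 2D mask")
  bb <- mask_bbox(m)
  if (is.null(bb))
    return(data.frame(y = integer(0), x = integer(0)))
  ys <- seq(bb$r0, bb$r1, by = cfg$grid_spacing)
  xs <- seq(bb$c0, bb$c1, by = cfg$grid_spacing)
  g <- expand.grid(y = ys, x = xs)
  keep <- m[cbind(g$y + 1, g$x + 1)]
  g[keep, , drop = FALSE]
}

#' Background-class sample points of one annotated slice
#'
#' The allowed region is the image minus (i) the mask dilated by a Euclidean
#' disk of radius `dilation_radius`, (ii) the horizontal strip spanning the
#' mask's row range and (iii) the vertical strip spanning its column range,
#' both strips enlarged by `strip_pad` px in each direction.  Grid points
#' (pitch `grid_spacing`, anchored at the image origin) inside the allowed
#' region are returned.  By construction no BC point's sagittal or coronal
#' ray intersects the organ.
#'
#' @inheritParams organ_points
#' @return data.frame with 0-based columns `y`, `x`.
#' @export
background_points <- function(mask, cfg = sampling_config()) {
  m <- mask_data(mask)
  if (length(dim(m)) != 2) stop("background_points expects a 2D mask")
  nr <- nrow(m); nc <- ncol(m)
  ys <- seq(0, nr - 1, by = cfg$grid_spacing)
  xs <- seq(0, nc - 1, by = cfg$grid_spacing)
  g <- expand.grid(y = ys, x = xs)
  bb <- mask_bbox(m)
  if (is.null(bb)) return(g)
  dil <- dilate_disk(m, cfg$dilation_radius)
  row_strip <- g$y >= bb$r0 - cfg$strip_pad & g$y <= bb$r1 + cfg$strip_pad
  col_strip <- g$x >= bb$c0 - cfg$strip_pad & g$x <= bb$c1 + cfg$strip_pad
  in_dil <- dil[cbind(g$y + 1, g$x + 1)]
  g[!(row_strip | col_strip | in_dil), , drop = FALSE]
}

# Along-axis organ points: one point per grid_spacing of mask height placed
# at the center column of the row's mask support (plus the terminal bottom
# row), and symmetrically one per grid_spacing of mask width at the center
# row of the column's support (plus the terminal right column).  This is
# the complementary reading of "equidistant every 50 px along the Y axis":
# a point sequence along the axis, always inside the mask.  The pure
# 2D-grid reading concentrates its surviving in-mask points at the organ's
# widest rows (grid pitch ~ organ size), leaving the organ's edge bands
# unrepresented in the training set; the union of both readings covers the
# organ evenly out to its extremes, which is what edge-line recall of the
# per-axis classifiers depends on.
organ_line_points <- function(mask, cfg = sampling_config()) {
  m <- mask_data(mask)
  bb <- mask_bbox(m)
  empty <- data.frame(y = integer(0), x = integer(0))
  if (is.null(bb)) return(empty)
  ys <- unique(c(seq(bb$r0, bb$r1, by = cfg$grid_spacing), bb$r1))
  xs <- unique(c(seq(bb$c0, bb$c1, by = cfg$grid_spacing), bb$c1))
  row_pts <- lapply(ys, function(y) {
    cols <- which(m[y + 1, ])
    if (!length(cols)) return(NULL)
    data.frame(y = y, x = cols[ceiling(length(cols) / 2)] - 1L)
  })
  col_pts <- lapply(xs, function(x) {
    rows <- which(m[, x + 1])
    if (!length(rows)) return(NULL)
    data.frame(y = rows[ceiling(length(rows) / 2)] - 1L, x = x)
  })
  out <- do.call(rbind, c(row_pts, col_pts))
  if (is.null(out)) empty else unique(out)
}

# which image half an organ occupies (radiological convention: the right
# kidney shows on the left image half)
organ_side <- function(label) {
  switch(label,
         kidney_right = "left",
         kidney_left = "right",
         spleen = "right",
         "full")
}

#' Extract the three projection images of a 3D point
#'
#' `img_x`: sagittal plane at the point's x (z rows, y columns), depth
#' resampled to `target_z` rows.  `img_y`: coronal plane at the point's y
#' (z rows, x columns), cropped to the organ's image half when
#' `side != "full"`, then depth resampled.  `img_z`: the full axial slice.
#'
#' @param vol a normalized `ct_volume`.
#' @param p list/row with 0-based `x`, `y`, `z`.
#' @param side `"left"`, `"right"` or `"full"` (the organ's image half).
#' @param target_z row count of the resampled projections (default 43).
#' @return `list(img_x, img_y, img_z)` of matrices.
#' @export
extract_triplet <- function(vol, p, side = "full", target_z = 43) {
  d <- dim(vol$data)
  if (p$z < 0 || p$z >= d[1] || p$y < 0 || p$y >= d[2] || p$x < 0 || p$x >= d[3])
    stop("point (", p$z, ",", p$y, ",", p$x, ") outside the volume")
  img_x <- resample_depth(vol$data[, , p$x + 1], target_z)
  img_y <- resample_depth(crop_half(vol$data[, p$y + 1, ], side), target_z)
  img_z <- vol$data[p$z + 1, , ]
  list(img_x = img_x, img_y = img_y, img_z = img_z)
}

#' Build the three per-axis training sets from a labeled cohort
#'
#' For every annotated axial slice (stride `cfg$slice_stride`) of every case,
#' OC and BC points are generated from the expert mask and each point
#' contributes its sagittal image to the X set and its (half-cropped)
#' coronal image to the Y set, labeled by the point's class.  The Z set
#' contains axial slices (stride `cfg$z_stride`), labeled organ when the
#' slice intersects the 3D mask and background otherwise.
#'
#' @param cohort list of `list(volume, masks)` as from [make_cohort()].
#' @param organ organ label to train for; cases lacking it are skipped with
#'   a warning.
#' @param cfg a [sampling_config()].
#' @param target_z projection row count (default 43).
#' @param seed RNG seed for the `bc_max` subsample.
#' @return list with elements `X`, `Y`, `Z`; each holds `images`
#'   (H x W x N array), `labels` (factor `background`/`organ`) and `meta`
#'   (case/z/y/x bookkeeping).
#' @export
build_dataset <- function(cohort, organ, cfg = sampling_config(),
                          target_z = 43, seed = 1L) {
  side <- organ_side(organ)
  set.seed(seed)
  xs_imgs <- list(); ys_imgs <- list(); zs_imgs <- list()
  xs_lab <- character(0); ys_lab <- character(0); zs_lab <- character(0)
  meta <- list(X = list(), Y = list(), Z = list())

  for (ci in seq_along(cohort)) {
    case <- cohort[[ci]]
    if (is.null(case$masks[[organ]])) {
      warning("case ", ci, " lacks an annotation for '", organ, "'; skipped")
      next
    }
    vol <- case$volume
    m3 <- case$masks[[organ]]$data
    nz <- dim(m3)[1]
    ann <- which(apply(m3, 1, any))          # annotated slices, 1-based
    sel <- ann[seq(1, length(ann), by = cfg$slice_stride)]

    # caches: the sagittal image depends on x only, the coronal on y only
    cache_x <- new.env(parent = emptyenv())
    cache_y <- new.env(parent = emptyenv())
    img_x_of <- function(x) {
      k <- as.character(x)
      if (is.null(cache_x[[k]]))
        cache_x[[k]] <- resample_depth(vol$data[, , x + 1], target_z)
      cache_x[[k]]
    }
    img_y_of <- function(y) {
      k <- as.character(y)
      if (is.null(cache_y[[k]]))
        cache_y[[k]] <- resample_depth(crop_half(vol$data[, y + 1, ], side),
                                       target_z)
      cache_y[[k]]
    }

    for (zi in sel) {
      sl <- m3[zi, , ]
      oc <- unique(rbind(organ_points(sl, cfg), organ_line_points(sl, cfg)))
      bc <- background_points(sl, cfg)
      # only one organ is analyzed at a time: scanning is restricted to its
      # image half, so training points stay in that half as well (a sagittal
      # plane through the mirrored organ is indistinguishable from a positive
      # and must not enter the set as a background label)
      half <- dim(sl)[2] / 2
      keep <- switch(side, left = bc$x < half, right = bc$x >= half,
                     full = rep(TRUE, nrow(bc)))
      bc <- bc[keep, , drop = FALSE]
      if (is.finite(cfg$bc_max) && nrow(bc) > cfg$bc_max)
        bc <- bc[sort(sample.int(nrow(bc), cfg$bc_max)), , drop = FALSE]
      pts <- rbind(cbind(oc, label = if (nrow(oc)) "organ" else character(0)),
                   cbind(bc, label = if (nrow(bc)) "background" else character(0)))
      for (r in seq_len(nrow(pts))) {
        xs_imgs[[length(xs_imgs) + 1L]] <- img_x_of(pts$x[r])
        ys_imgs[[length(ys_imgs) + 1L]] <- img_y_of(pts$y[r])
        xs_lab <- c(xs_lab, pts$label[r])
        ys_lab <- c(ys_lab, pts$label[r])
        meta$X[[length(meta$X) + 1L]] <-
          data.frame(case = ci, z = zi - 1L, y = pts$y[r], x = pts$x[r],
                     label = pts$label[r])
        meta$Y[[length(meta$Y) + 1L]] <- meta$X[[length(meta$X)]]
      }
    }

    in_z_cases <- ci <= (cfg$z_cases %||% Inf)
    zsel <- if (in_z_cases) seq(1, nz, by = cfg$z_stride) else integer(0)
    if (in_z_cases && cfg$z_margin > 0 && length(ann)) {
      edges <- c(min(ann), max(ann))
      zsel <- sort(unique(c(zsel,
                            pmax(1, pmin(nz, outer(edges,
                                                   -cfg$z_margin:cfg$z_margin,
                                                   `+`))))))
    }
    for (zi in zsel) {
      zs_imgs[[length(zs_imgs) + 1L]] <- vol$data[zi, , ]
      lb <- if (any(m3[zi, , ])) "organ" else "background"
      zs_lab <- c(zs_lab, lb)
      meta$Z[[length(meta$Z) + 1L]] <-
        data.frame(case = ci, z = zi - 1L, y = NA, x = NA, label = lb)
    }
  }

  pack <- function(imgs, labs, mt) {
    if (!length(imgs))
      return(list(images = array(0, c(0, 0, 0)),
                  labels = factor(character(0),
                                  levels = c("background", "organ")),
                  meta = data.frame()))
    d <- dim(imgs[[1]])
    arr <- array(0, c(d[1], d[2], length(imgs)))
    for (i in seq_along(imgs)) arr[, , i] <- imgs[[i]]
    list(images = arr,
         labels = factor(labs, levels = c("background", "organ")),
         meta = do.call(rbind, mt))
  }
  list(X = pack(xs_imgs, xs_lab, meta$X),
       Y = pack(ys_imgs, ys_lab, meta$Y),
       Z = pack(zs_imgs, zs_lab, meta$Z))
}

#' Persist a per-axis dataset as PNG images plus a CSV manifest
#'
#' @param dataset one axis element of [build_dataset()]'s result.
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to export datasets")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$labels)
  files <- sprintf("img_%05d.png", seq_len(n))
  for (i in seq_len(n))
    png::writePNG(pmin(pmax(dataset$images[, , i], 0), 1),
                  file.path(dir, files[i]))
  manifest <- cbind(dataset$meta, file = files)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Load a dataset written by [write_dataset()]
#' @param dir dataset directory containing `manifest.csv`.
#' @return the same structure as one axis of [build_dataset()].
#' @export
read_dataset <- function(dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to import datasets")
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  imgs <- lapply(file.path(dir, manifest$file), function(f) {
    im <- png::readPNG(f)
    if (length(dim(im)) == 3) im <- im[, , 1]
    im
  })
  d <- dim(imgs[[1]])
  arr <- array(0, c(d[1], d[2], length(imgs)))
  for (i in seq_along(imgs)) arr[, , i] <- imgs[[i]]
  list(images = arr,
       labels = factor(manifest$label, levels = c("background", "organ")),
       meta = manifest[setdiff(names(manifest), "file")])
}
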