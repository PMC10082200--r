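# 2D morphology built on the exact EDT and component labelling in src/.
# All functions take and return plain logical matrices; callers own the
# 0-based/1-based bookkeeping.

# Euclidean disk dilation: true wherever the distance to the mask is <= r.
dilate_disk <- function(mask, radius) {
  if (!any(mask)) return(mask)
  d2 <- edt_sq_cpp(mask, dim(mask), rep(1, length(dim(mask))))
  array(d2 <= radius^2, dim = dim(mask))
}

# Square dilation with a centered structuring element, separable per axis.
# Even sizes use offsets [-size/2, size/2 - 1], so a single pixel grows to a
# square of exactly size x size whose upper-left quadrant is one pixel larger.
dilate_square <- function(mask, size) {
  lo <- -floor(size / 2)
  hi <- size - 1 + lo
  nr <- nrow(mask); nc <- ncol(mask)
  tmp <- matrix(FALSE, nr, nc)
  # out(r) = any o in [lo, hi] with in(r - o)   (0-based rows)
  for (o in lo:hi) {
    src <- (1:nr) - 1 - o
    ok <- src >= 0 & src <= nr - 1
    tmp[which(ok), ] <- tmp[which(ok), , drop = FALSE] |
      mask[src[ok] + 1, , drop = FALSE]
  }
  out <- matrix(FALSE, nr, nc)
  for (o in lo:hi) {
    src <- (1:nc) - 1 - o
    ok <- src >= 0 & src <= nc - 1
    out[, which(ok)] <- out[, which(ok), drop = FALSE] |
      tmp[, src[ok] + 1, drop = FALSE]
  }
  out
}

# Keep only the largest connected component (8-connectivity by default).
# Ties resolve to the component discovered first in column-major order.
largest_component <- function(mask, connectivity = 8) {
  if (!any(mask)) return(mask)
  lab <- label_components_cpp(mask, connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  lab == keep
}

# Fill interior holes: background regions (8-connected) that do not touch
# the image border become foreground.
fill_holes <- function(mask, connectivity = 8) {
  bg <- !mask
  lab <- label_components_cpp(bg, connectivity)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  mask | (bg & !(lab %in% border))
}
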