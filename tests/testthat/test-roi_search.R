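# stub rule used across these tests: a projection is "organ" when it shows
# any bright voxel
bright_stub <- function(axis) {
  stub_classifier(function(imgs) {
    apply(imgs, 3, function(im) as.numeric(any(im > 0.5)))
  }, axis = axis)
}

make_box_volume <- function(dim = c(50, 64, 64),
                            z = 11:31, y = 21:41, x = 16:46) {
  arr <- array(0, dim = dim)
  arr[z, y, x] <- 1
  ct_volume(arr, normalized = TRUE)
}

test_that("positive_grid is the Cartesian AND of the flag vectors", {
  fl <- function(axis, coords, flags)
    structure(list(axis = axis, coords = coords, flags = flags, step = 10L),
              class = "axis_flags")
  xf <- fl("X", seq(0, 90, 10), rep(c(TRUE, FALSE), c(3, 7)))
  yf <- fl("Y", seq(0, 90, 10), rep(c(FALSE, TRUE, FALSE), c(4, 2, 4)))
  zf <- fl("Z", 0:9, rep(c(TRUE, FALSE), c(4, 6)))
  g <- positive_grid(xf, yf, zf)
  expect_identical(nrow(g), 3L * 2L * 4L)
  expect_true(all(g$x %in% c(0, 10, 20)))

  zf_none <- fl("Z", 0:9, rep(FALSE, 10))
  expect_identical(nrow(positive_grid(xf, yf, zf_none)), 0L)
})

test_that("flag vectors have ceil(extent/step) entries and line semantics", {
  vol <- make_box_volume()
  cfg <- search_config(scan_step = 10, side = "full", z_step = 1)
  xf <- classify_axis_lines(vol, "X", bright_stub("X"), cfg)
  expect_length(xf$flags, ceiling(64 / 10))
  expect_identical(xf$coords, as.integer(seq(0, 60, 10)))
  # box x extent is [15, 46]: lines 20..40 positive, 0..10 and 50..60 not
  expect_identical(xf$coords[xf$flags], as.integer(c(20, 30, 40)))
  zf <- classify_axis_lines(vol, "Z", bright_stub("Z"), cfg)
  expect_length(zf$flags, 50)
  expect_error(classify_axis_lines(vol, "Y", bright_stub("X"), cfg),
               "axis")
})

test_that("exclusion scan equals brute-force triple classification", {
  vol <- make_box_volume()
  cfg <- search_config(scan_step = 10, side = "full", z_step = 10)
  nets <- list(X = bright_stub("X"), Y = bright_stub("Y"),
               Z = bright_stub("Z"))
  xf <- classify_axis_lines(vol, "X", nets$X, cfg)
  yf <- classify_axis_lines(vol, "Y", nets$Y, cfg)
  zf <- classify_axis_lines(vol, "Z", nets$Z, cfg)
  fast <- positive_grid(xf, yf, zf)

  brute <- NULL
  for (z in zf$coords) for (y in yf$coords) for (x in xf$coords) {
    tr <- extract_triplet(vol, list(z = z, y = y, x = x), side = "full")
    ok <- any(tr$img_x > 0.5) && any(tr$img_y > 0.5) && any(tr$img_z > 0.5)
    if (ok) brute <- rbind(brute, c(x, y, z))
  }
  fast_s <- fast[order(fast$z, fast$y, fast$x), ]
  brute <- brute[order(brute[, 3], brute[, 2], brute[, 1]), , drop = FALSE]
  expect_identical(nrow(fast_s), nrow(brute))
  expect_equal(unname(as.matrix(fast_s)), unname(brute), ignore_attr = TRUE)
})

test_that("merge_points rasterizes segments between grid neighbors", {
  cfg <- search_config()
  seg <- merge_points(data.frame(y = c(100, 100), x = c(100, 110)), cfg,
                      dim = c(512, 512))
  expect_identical(sum(seg), 11L)
  expect_true(all(seg[101, 101:111]))

  single <- merge_points(data.frame(y = 30, x = 40), cfg, dim = c(64, 64))
  expect_identical(sum(single), 1L)
  expect_true(single[31, 41])

  # a full k x k positive block becomes one connected component spanning it
  block <- expand.grid(y = seq(100, 140, 10), x = seq(200, 250, 10))
  bm <- merge_points(block, cfg, dim = c(512, 512))
  lab <- ctroi:::label_components_cpp(bm, 8)
  expect_identical(max(lab), 1L)
  expect_identical(range(which(rowSums(bm) > 0)), c(101L, 141L))
  expect_identical(range(which(colSums(bm) > 0)), c(201L, 251L))
})

test_that("refine_mask keeps the largest component then dilates", {
  m <- matrix(FALSE, 300, 300)
  m[10:14, 10] <- TRUE                        # 5 px component
  m[101:110, 101:105] <- TRUE                 # 50 px component
  out <- refine_mask(m, search_config())
  # the small component must not survive (check far from the dilated big one)
  expect_false(any(out[1:30, 1:30]))
  expect_true(all(out[101:110, 101:105]))     # dilation is extensive
  # bounds: [-15, +14] around the large component
  expect_identical(range(which(rowSums(out) > 0)), c(101L - 15L, 110L + 14L))

  single <- matrix(FALSE, 400, 400); single[201, 201] <- TRUE
  ds <- refine_mask(single, search_config())
  expect_identical(sum(ds), 900L)             # 30 x 30 square
  expect_identical(range(which(rowSums(ds) > 0)), c(186L, 215L))

  expect_warning(out0 <- refine_mask(matrix(FALSE, 5, 5), search_config()),
                 "empty")
  expect_false(any(out0))
})

test_that("find_roi bounds the box and grows with dilate_size", {
  vol <- make_box_volume()
  nets <- list(X = bright_stub("X"), Y = bright_stub("Y"),
               Z = bright_stub("Z"))
  cfg <- search_config(scan_step = 4, merge_distance = 4, dilate_size = 6,
                       side = "full")
  roi <- find_roi(vol, nets, cfg)
  expect_s3_class(roi, "roi_box")
  # ROI must contain the full box (z padded by one slice)
  mask <- array(FALSE, c(50, 64, 64)); mask[11:31, 21:41, 16:46] <- TRUE
  expect_equal(roi_coverage(roi, mask), 1)
  # monotonicity: a larger structuring element never shrinks the box
  roi2 <- find_roi(vol, nets, search_config(scan_step = 4, merge_distance = 4,
                                            dilate_size = 10, side = "full"))
  expect_true(roi2$x0 <= roi$x0 && roi2$x1 >= roi$x1 &&
                roi2$y0 <= roi$y0 && roi2$y1 >= roi$y1)

  # organ-free volume: detection failure naming the organ
  empty_vol <- ct_volume(array(0, c(50, 64, 64)), normalized = TRUE)
  expect_error(find_roi(empty_vol, nets, cfg, organ = "kidney_right"),
               "kidney_right")
})

test_that("roi boxes serialize to JSON and back", {
  roi <- roi_box(10, 20, 30, 40, 1, 5)
  f <- withr::local_tempfile(fileext = ".json")
  write_roi(roi, f, extra = list(organ = "spleen"))
  r2 <- read_roi(f)
  expect_identical(unclass(r2), unclass(roi))
  expect_error(roi_box(5, 5, 0, 1, 0, 1), "x0<x1")
})
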