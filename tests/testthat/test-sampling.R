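test_that("organ_points lays a bbox-anchored grid inside the mask", {
  m <- matrix(FALSE, 200, 200)
  m[1:120, 1:60] <- TRUE                     # rows 0..119, cols 0..59
  pts <- organ_points(m, sampling_config())
  expect_identical(nrow(pts), 6L)
  expect_setequal(paste(pts$y, pts$x),
                  paste(rep(c(0, 50, 100), 2), rep(c(0, 50), each = 3)))

  expect_identical(nrow(organ_points(matrix(FALSE, 50, 50))), 0L)

  single <- matrix(FALSE, 300, 300); single[101, 141] <- TRUE
  sp <- organ_points(single)
  expect_identical(unname(unlist(sp)), c(100L, 140L))
})

test_that("background_points excludes the dilated mask and both strips", {
  m <- matrix(FALSE, 512, 512); m[201, 201] <- TRUE     # pixel (200,200)
  pts <- background_points(m, sampling_config())
  expect_identical(nrow(pts), 100L)
  expect_true(all(pts$y %% 50 == 0 & pts$x %% 50 == 0))
  expect_false(any(pts$y >= 180 & pts$y <= 220))
  expect_false(any(pts$x >= 180 & pts$x <= 220))

  # empty mask: nothing excluded, full 11 x 11 grid
  expect_identical(nrow(background_points(matrix(FALSE, 512, 512))), 121L)

  # every point's sagittal and coronal ray misses the mask
  blob <- matrix(FALSE, 512, 512); blob[230:300, 140:190] <- TRUE
  bp <- background_points(blob, sampling_config())
  for (i in seq_len(nrow(bp))) {
    expect_false(any(blob[bp$y[i] + 1, ]))
    expect_false(any(blob[, bp$x[i] + 1]))
  }
})

test_that("point generators match brute-force region enumeration", {
  cfg <- sampling_config(grid_spacing = 7, dilation_radius = 9, strip_pad = 3)
  set.seed(14)
  for (rep in 1:5) {
    m <- matrix(FALSE, 60, 75)
    r0 <- sample(10:30, 1); c0 <- sample(10:40, 1)
    m[r0:(r0 + sample(5:15, 1)), c0:(c0 + sample(5:12, 1))] <- TRUE

    # OC oracle: every grid point of the bbox-anchored lattice inside the mask
    bb <- ctroi:::mask_bbox(m)
    oc_oracle <- NULL
    for (y in seq(bb$r0, bb$r1, by = 7)) for (x in seq(bb$c0, bb$c1, by = 7))
      if (m[y + 1, x + 1]) oc_oracle <- rbind(oc_oracle, c(y, x))
    oc <- organ_points(m, cfg)
    oc <- oc[order(oc$y, oc$x), ]
    oc_oracle <- oc_oracle[order(oc_oracle[, 1], oc_oracle[, 2]), , drop = FALSE]
    expect_equal(unname(as.matrix(oc)), unname(oc_oracle),
                 ignore_attr = TRUE)

    # BC oracle: origin lattice, Euclidean distance to mask > 9, outside strips
    mask_idx <- which(m, arr.ind = TRUE) - 1
    bc_oracle <- NULL
    for (y in seq(0, 59, by = 7)) for (x in seq(0, 74, by = 7)) {
      dmin <- sqrt(min((mask_idx[, 1] - y)^2 + (mask_idx[, 2] - x)^2))
      in_row <- y >= bb$r0 - 3 && y <= bb$r1 + 3
      in_col <- x >= bb$c0 - 3 && x <= bb$c1 + 3
      if (dmin > 9 && !in_row && !in_col)
        bc_oracle <- rbind(bc_oracle, c(y, x))
    }
    bc <- background_points(m, cfg)
    bc <- bc[order(bc$y, bc$x), ]
    bc_oracle <- bc_oracle[order(bc_oracle[, 1], bc_oracle[, 2]), , drop = FALSE]
    expect_equal(unname(as.matrix(bc)), unname(bc_oracle),
                 ignore_attr = TRUE)
  }
})

test_that("OC and BC points stay apart by the dilation/grid margin", {
  ph <- get_clean_phantom()
  m3 <- ph$masks$kidney_right$data
  zmid <- round(mean(which(apply(m3, 1, any))))
  sl <- m3[zmid, , ]
  cfg <- sampling_config()
  oc <- organ_points(sl, cfg)
  bc <- background_points(sl, cfg)
  expect_gt(nrow(oc), 0); expect_gt(nrow(bc), 0)
  mask_idx <- which(sl, arr.ind = TRUE) - 1
  min_bc_dist <- min(vapply(seq_len(nrow(bc)), function(i)
    sqrt(min((mask_idx[, 1] - bc$y[i])^2 + (mask_idx[, 2] - bc$x[i])^2)),
    numeric(1)))
  expect_gte(min_bc_dist, cfg$dilation_radius - cfg$grid_spacing)
  # and the two point sets are disjoint
  expect_length(intersect(paste(oc$y, oc$x), paste(bc$y, bc$x)), 0)
})

test_that("extract_triplet produces the contracted shapes and content", {
  ph <- get_clean_phantom()
  vol <- ph$volume
  organ_val <- 0.65                         # clean phantom kidney intensity
  m3 <- ph$masks$kidney_right$data
  inside <- which(m3, arr.ind = TRUE)[1, ] - 1

  tr <- extract_triplet(vol, list(z = inside[1], y = inside[2], x = inside[3]),
                        side = "left")
  expect_identical(dim(tr$img_x), c(43L, 512L))
  expect_identical(dim(tr$img_y), c(43L, 256L))
  expect_identical(dim(tr$img_z), c(512L, 512L))
  expect_gt(sum(tr$img_x == organ_val), 0)   # elliptical cross-section present
  expect_gt(sum(tr$img_y == organ_val), 0)

  # a BC-region point far from the organ sees no organ voxels
  tr_bc <- extract_triplet(vol, list(z = 21, y = 30, x = 30), side = "left")
  expect_identical(sum(tr_bc$img_x == organ_val), 0L)
  expect_identical(sum(tr_bc$img_y == organ_val), 0L)

  # the sagittal image depends on x only
  tr2 <- extract_triplet(vol, list(z = 3, y = 400, x = inside[3]), side = "left")
  expect_identical(tr2$img_x, tr$img_x)

  expect_error(extract_triplet(vol, list(z = 0, y = 0, x = 512), "left"),
               "outside")
})

test_that("build_dataset assembles labeled per-axis sets with right counts", {
  cohort <- make_cohort(1, micro_spec(), seed = 3)
  cfg <- sampling_config(grid_spacing = 10, dilation_radius = 12,
                         strip_pad = 4, slice_stride = 2, z_stride = 1)
  ds <- build_dataset(cohort, "kidney_right", cfg, target_z = 16, seed = 1)

  m3 <- cohort[[1]]$masks$kidney_right$data
  ann <- which(apply(m3, 1, any))
  sel <- ann[seq(1, length(ann), by = 2)]
  # OC = grid points union along-axis line points; BC restricted to the
  # organ image half (left for the right kidney)
  expected <- sum(vapply(sel, function(zi) {
    sl <- m3[zi, , ]
    oc <- unique(rbind(organ_points(sl, cfg),
                       ctroi:::organ_line_points(sl, cfg)))
    bc <- background_points(sl, cfg)
    nrow(oc) + sum(bc$x < ncol(sl) / 2)
  }, numeric(1)))
  expect_identical(length(ds$X$labels), as.integer(expected))
  expect_identical(length(ds$Y$labels), as.integer(expected))
  expect_identical(dim(ds$X$images)[1:2], c(16L, 64L))
  expect_identical(dim(ds$Y$images)[1:2], c(16L, 32L))

  # Z set: one image per slice, labeled by mask intersection
  expect_identical(length(ds$Z$labels), 16L)
  expect_identical(as.vector(table(ds$Z$labels)["organ"]),
                   length(ann))

  # deterministic under a fixed cohort
  ds2 <- build_dataset(cohort, "kidney_right", cfg, target_z = 16, seed = 1)
  expect_identical(ds$X$images, ds2$X$images)
  expect_identical(ds$X$labels, ds2$X$labels)

  # every OC-labeled coronal image contains organ intensities of that case
  oc_rows <- which(ds$Y$labels == "organ")
  for (i in oc_rows[seq_len(min(5, length(oc_rows)))]) {
    y <- ds$Y$meta$y[i]
    expect_true(any(m3[, y + 1, 1:32]))
  }

  # a case without the requested organ is skipped with a warning
  expect_warning(
    ds3 <- build_dataset(cohort, "spleen", cfg, target_z = 16),
    "lacks an annotation")
  expect_identical(length(ds3$X$labels), 0L)
})
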