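test_that("two-intensity images split exactly at the Lloyd fixed point", {
  img <- matrix(c(rep(0.1, 10), rep(0.9, 10)), 4, 5)
  res <- cluster_roi(img, cluster_config(n_c = 2))
  expect_equal(sort(res$centers), c(0.1, 0.9))
  expect_identical(sort(unname(res$counts)), c(10L, 10L))
  expect_true(all((img == 0.1) == (res$labels == res$labels[img == 0.1][1])))

  # single cluster: center is the image mean
  res1 <- cluster_roi(img, cluster_config(n_c = 1))
  expect_equal(res1$centers, mean(img))
  expect_true(all(res1$labels == 1))

  # fewer distinct intensities than clusters: reduced with a warning
  expect_warning(res2 <- cluster_roi(img, cluster_config(n_c = 7)),
                 "fewer distinct")
  expect_lte(length(res2$centers), 2)
})

test_that("the within-cluster objective never increases across iterations", {
  set.seed(33)
  img <- matrix(runif(400), 20, 20)
  res <- cluster_roi(img, cluster_config(n_c = 5))
  expect_true(all(diff(res$objective) <= 1e-12))
  # every pixel carries exactly one label; centers are member means
  expect_true(all(res$labels %in% seq_along(res$centers)))
  for (j in seq_along(res$centers))
    expect_equal(res$centers[j], mean(img[res$labels == j]), tolerance = 1e-3)
})

test_that("cluster_roi matches an independent Lloyd reference label-for-label", {
  set.seed(77)
  for (rep in 1:20) {
    npx <- 4 * sample(2:16, 1)
    v <- round(runif(npx), 3)
    img <- matrix(v, nrow = sample(c(1, 2, 4), 1))
    k <- sample(2:5, 1)
    res <- suppressWarnings(
      cluster_roi(img, cluster_config(n_c = k, merge_alpha = 0)))
    ref <- reference_lloyd(as.vector(img), k)
    nonempty <- sort(unique(ref$labels))
    remap <- match(ref$labels, nonempty)
    expect_identical(as.vector(res$labels), remap)
    expect_equal(res$centers, ref$centers[nonempty], tolerance = 1e-12)
  }
})

test_that("select_cluster prefers central clusters, then larger ones", {
  lab <- matrix(2L, 21, 21)
  lab[8:14, 8:14] <- 1L                     # compact centered blob
  res <- structure(list(labels = lab, centers = c(0.8, 0.2),
                        counts = c(sum(lab == 1), sum(lab == 2))),
                   class = "cluster_result")
  sel <- select_cluster(res)
  expect_true(all(sel == (lab == 1)))

  # exact tie in mean member distance, unequal sizes: on a 3x3 window the
  # two vertical edge cells (cluster 1) and one horizontal edge cell
  # (cluster 2) all sit at distance 1 from the center
  lab2 <- matrix(3L, 3, 3)
  lab2[1, 2] <- 1L; lab2[3, 2] <- 1L        # mean distance 1, count 2
  lab2[2, 1] <- 2L                          # mean distance 1, count 1
  res2 <- structure(list(labels = lab2, centers = c(0.1, 0.5, 0.9),
                         counts = c(2L, 1L, 6L)),
                    class = "cluster_result")
  sel2 <- select_cluster(res2)
  expect_true(all(sel2 == (lab2 == 1)))     # tie broken by larger count
})

test_that("postprocess_mask clips, fills holes and keeps one component", {
  ring <- matrix(FALSE, 20, 20)
  ring[5:15, 5:15] <- TRUE
  ring[8:12, 8:12] <- FALSE
  filled <- postprocess_mask(ring)
  expect_true(all(filled[5:15, 5:15]))

  m <- matrix(FALSE, 30, 30)
  m[2:9, 2:9] <- TRUE                       # 64 px inside ROI
  m[25:26, 25:26] <- TRUE                   # 4 px outside ROI
  out <- postprocess_mask(m, roi = list(y0 = 0, y1 = 20, x0 = 0, x1 = 20))
  expect_true(all(out[2:9, 2:9]))
  expect_false(any(out[21:30, ]))

  two <- matrix(FALSE, 30, 30)
  two[2:9, 2:6] <- TRUE                     # 40 px
  two[20:21, 20:21] <- TRUE                 # 4 px
  out2 <- postprocess_mask(two)
  expect_true(all(out2[2:9, 2:6]))
  expect_false(any(out2[20:21, 20:21]))

  expect_warning(e <- postprocess_mask(matrix(FALSE, 5, 5)), "empty")
  expect_false(any(e))
})

test_that("segment_organ recovers noise-free ellipse sections exactly", {
  spec <- phantom_spec(shape = c(16, 64, 64),
                       organs = list(list(label = "kidney_right",
                                          center = c(8, 30, 16),
                                          semi = c(4, 10, 8),
                                          intensity = 0.65)),
                       distractors = list(), noise_sigma = 0,
                       texture_scale = 0, seed = 4)
  ph <- make_phantom(spec)
  m3 <- ph$masks$kidney_right$data
  # z bounds = exact organ extent so every ROI slice holds organ pixels
  roi <- roi_box(x0 = 4, x1 = 30, y0 = 16, y1 = 44, z0 = 4, z1 = 13)
  stopifnot(roi_coverage(roi, m3) == 1)
  seg <- suppressWarnings(
    segment_organ(ph$volume, roi, cluster_config(), label = "kidney_right"))
  expect_identical(seg$data, m3)
  # and the prediction always stays inside the cube
  outside <- seg$data
  outside[(roi$z0 + 1):roi$z1, (roi$y0 + 1):roi$y1, (roi$x0 + 1):roi$x1] <- FALSE
  expect_false(any(outside))

  # determinism under a fixed config
  seg2 <- suppressWarnings(
    segment_organ(ph$volume, roi, cluster_config(), label = "kidney_right"))
  expect_identical(seg$data, seg2$data)
})
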