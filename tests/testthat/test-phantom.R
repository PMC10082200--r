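test_that("ellipsoid mask matches brute-force voxel enumeration", {
  spec <- phantom_spec(shape = c(12, 30, 34),
                       organs = list(list(label = "spleen",
                                          center = c(6, 15, 18),
                                          semi = c(4, 7, 6),
                                          intensity = 0.7)),
                       distractors = list(), noise_sigma = 0,
                       texture_scale = 0, seed = 2)
  ph <- make_phantom(spec)
  brute <- 0L
  for (z in 0:11) for (y in 0:29) for (x in 0:33)
    if (((z - 6) / 4)^2 + ((y - 15) / 7)^2 + ((x - 18) / 6)^2 <= 1) {
      brute <- brute + 1L
      expect_true(ph$masks$spleen$data[z + 1, y + 1, x + 1])
    }
  expect_identical(sum(ph$masks$spleen$data), brute)
  # with zero noise the in-mask mean equals the specified intensity exactly
  expect_equal(mean(ph$volume$data[ph$masks$spleen$data]), 0.7)
})

test_that("phantoms are reproducible and validate their spec", {
  spec <- phantom_spec(shape = c(10, 48, 48),
                       organs = list(list(label = "kidney_right",
                                          center = c(5, 24, 14),
                                          semi = c(3, 8, 6),
                                          intensity = 0.6)),
                       distractors = list(), seed = 9)
  a <- make_phantom(spec); b <- make_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$masks$kidney_right$data, b$masks$kidney_right$data)

  # no organs: masks empty, volume is background + texture + noise
  empty <- phantom_spec(shape = c(8, 32, 32), organs = list(),
                        distractors = list(), seed = 1)
  ph <- make_phantom(empty)
  expect_length(ph$masks, 0)
  expect_equal(mean(ph$volume$data), empty$background_mean, tolerance = 0.02)

  # out-of-grid ellipsoid and unlearnable contrast are spec errors
  expect_error(phantom_spec(shape = c(8, 32, 32),
                            organs = list(list(label = "spleen",
                                               center = c(4, 16, 30),
                                               semi = c(2, 4, 6),
                                               intensity = 0.7)),
                            distractors = list()),
               "outside the grid")
  expect_error(phantom_spec(shape = c(8, 32, 32),
                            organs = list(list(label = "spleen",
                                               center = c(4, 16, 16),
                                               semi = c(2, 4, 4),
                                               intensity = 0.35)),
                            distractors = list(), noise_sigma = 0.05),
               "3\\*noise_sigma")
})

test_that("cohorts are seeded, jittered and always contain every organ", {
  spec <- micro_spec()
  c1 <- make_cohort(3, spec, seed = 21)
  c2 <- make_cohort(3, spec, seed = 21)
  for (i in 1:3) {
    expect_identical(c1[[i]]$volume$data, c2[[i]]$volume$data)
    expect_gt(sum(c1[[i]]$masks$kidney_right$data), 0)
    expect_identical(dim(c1[[i]]$masks$kidney_right$data),
                     dim(c1[[i]]$volume$data))
  }
  # jitter actually moves the organ between cases
  expect_false(identical(c1[[1]]$masks$kidney_right$data,
                         c1[[2]]$masks$kidney_right$data))
  expect_error(make_cohort(0, spec), "n must be")
})
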