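# builds a mask pair over a flat grid with exact TP/FP/FN counts
mask_pair <- function(tp, fp, fn, total = 4000) {
  stopifnot(tp + fp + fn <= total)
  pred <- array(FALSE, c(total, 1, 1))
  ref <- array(FALSE, c(total, 1, 1))
  pred[seq_len(tp + fp)] <- TRUE
  ref[c(seq_len(tp), tp + fp + seq_len(fn))] <- TRUE
  list(pred = pred, ref = ref)
}

test_that("overlap metrics hit their closed forms on constructed counts", {
  m <- mask_pair(2120, 225, 295)
  om <- overlap_metrics(m$pred, m$ref)
  expect_identical(c(om$TP, om$FP, om$FN), c(2120L, 225L, 295L))
  expect_equal(om$F1, 2 * 2120 / (2 * 2120 + 225 + 295) * 100)
  expect_equal(om$TPR, 2120 / (2120 + 295) * 100)
  expect_equal(om$PPV, 2120 / (2120 + 225) * 100)
  expect_equal(om$VOE, (1 - 2120 / (2120 + 225 + 295)) * 100)
  expect_equal(om$RVD, (2345 - 2415) / 2415 * 100)

  # the literal printed formulas, behind the flag
  om2 <- overlap_metrics(m$pred, m$ref, paper_formulas = TRUE)
  expect_equal(om2$TPR, 2120 / (2120 + 225) * 100)
  expect_equal(om2$PPV, om2$TN / (om2$TN + 225) * 100)

  # identical masks
  id <- overlap_metrics(m$ref, m$ref)
  expect_equal(c(id$F1, id$VOE, id$RVD), c(100, 0, 0))
  # disjoint masks
  dj <- mask_pair(0, 50, 60)
  dm <- overlap_metrics(dj$pred, dj$ref)
  expect_equal(c(dm$F1, dm$VOE), c(0, 100))

  expect_error(overlap_metrics(array(TRUE, c(2, 2, 2)),
                               array(FALSE, c(2, 2, 2))), "empty")
  expect_error(overlap_metrics(array(TRUE, c(2, 2, 2)),
                               array(TRUE, c(2, 2, 3))), "shape")
})

test_that("F1 is Dice x 100 and the VOE relation holds on random masks", {
  set.seed(55)
  for (rep in 1:25) {
    p <- random_mask(c(8, 9, 7), runif(1, 0.2, 0.6))
    r <- random_mask(c(8, 9, 7), runif(1, 0.2, 0.6))
    if (!any(r) || !any(p)) next
    om <- overlap_metrics(p, r)
    dice <- 2 * sum(p & r) / (sum(p) + sum(r))
    expect_equal(om$F1, dice * 100, tolerance = 1e-12)
    expect_equal(om$VOE, (1 - om$F1 / (200 - om$F1)) * 100, tolerance = 1e-9)
  }
})

test_that("surface metrics reproduce hand-computed distances", {
  a <- array(FALSE, c(9, 9, 9)); a[2, 2, 2] <- TRUE
  b <- array(FALSE, c(9, 9, 9)); b[2, 2, 5] <- TRUE
  sm <- surface_metrics(a, b)
  expect_equal(unname(sm), c(3, 3))

  # unit square vs the same square shifted by 3 columns (2D)
  sq1 <- matrix(FALSE, 12, 12); sq1[4:5, 4:5] <- TRUE
  sq2 <- matrix(FALSE, 12, 12); sq2[4:5, 7:8] <- TRUE
  sm2 <- surface_metrics(sq1, sq2)
  expect_equal(unname(sm2[["MSSD"]]), 3)

  idm <- surface_metrics(sq1, sq1)
  expect_equal(unname(idm), c(0, 0))

  # anisotropic spacing scales distances
  sm3 <- surface_metrics(a, b, spacing = c(1, 1, 2))
  expect_equal(unname(sm3), c(6, 6))

  expect_error(surface_metrics(a, array(FALSE, c(9, 9, 9))), "empty")
})

test_that("surface metrics agree with the all-pairs brute-force oracle", {
  set.seed(91)
  for (rep in 1:6) {
    d <- c(sample(5:9, 1), sample(5:9, 1), sample(5:9, 1))
    p <- random_mask(d, 0.35); r <- random_mask(d, 0.35)
    if (!any(p) || !any(r)) next
    fast <- surface_metrics(p, r)
    slow <- brute_surface_metrics(p, r)
    expect_equal(unname(fast), unname(slow), tolerance = 1e-9)
  }
})

test_that("evaluate_cohort averages per-case metrics", {
  m1 <- mask_pair(80, 10, 10, 500)
  m2 <- mask_pair(20, 30, 40, 500)
  tab <- evaluate_cohort(list(m1, m2), surface = FALSE)
  expect_identical(nrow(tab), 3L)
  f1a <- overlap_metrics(m1$pred, m1$ref)$F1
  f1b <- overlap_metrics(m2$pred, m2$ref)$F1
  expect_equal(tab$F1[3], mean(c(f1a, f1b)))
  # mean of per-case F1 differs from F1 of summed counts
  pooled <- 2 * 100 / (2 * 100 + 40 + 50) * 100
  expect_false(isTRUE(all.equal(tab$F1[3], pooled)))

  one <- evaluate_cohort(list(m1), surface = FALSE)
  expect_equal(one$F1[1], one$F1[2])

  perf <- evaluate_cohort(list(list(pred = m1$ref, ref = m1$ref),
                               list(pred = m1$ref, ref = m1$ref)))
  expect_equal(perf$F1, rep(100, 3))
  expect_equal(perf$ASSD, rep(0, 3))
  expect_equal(perf$MSSD, rep(0, 3))
})
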