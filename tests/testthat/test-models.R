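test_that("network census matches the fixed architecture", {
  net <- build_network(net_config(c(16, 24), seed = 1), "X")
  census <- table(net$layers$layer)
  expect_identical(unname(census[["conv"]]), 2L)
  expect_identical(unname(census[["batchnorm"]]), 3L)
  expect_identical(unname(census[["relu"]]), 3L)
  expect_identical(unname(census[["maxpool"]]), 2L)
  expect_identical(unname(census[["fullyconnected"]]), 1L)
  expect_identical(net$classes, c("background", "organ"))
})

test_that("builds are deterministic and parameter count follows the shape", {
  cfg <- net_config(c(16, 24), seed = 3)
  a <- build_network(cfg, "X"); b <- build_network(cfg, "X")
  expect_identical(a$par, b$par)
  np <- ctroi:::n_params(a)
  # conv1 9*32+32, conv2 9*32*32+32, fc (4*6*32)*2+2, 3 BN pairs
  expect_identical(np, as.integer(9 * 32 + 32 + 9 * 32 * 32 + 32 +
                                    (4 * 6 * 32) * 2 + 2 + 6 * 32))
  np2 <- ctroi:::n_params(build_network(net_config(c(32, 24), seed = 3), "X"))
  expect_gt(np2, np)
})

test_that("an untrained forward pass yields a valid probability pair", {
  net <- build_network(net_config(c(16, 16), seed = 2), "Z")
  p <- predict_axis(net, matrix(0, 16, 16))
  expect_identical(nrow(p), 1L)
  expect_equal(p$p_background + p$p_organ, 1, tolerance = 1e-6)
  expect_true(all(c(p$p_background, p$p_organ) >= 0))
})

test_that("a separable toy problem trains to 100% within 4 epochs", {
  set.seed(10)
  n <- 64
  imgs <- array(0, c(16, 16, 2 * n))
  for (i in 1:n) imgs[, , i] <- 0.2 + rnorm(256, 0, 0.02)
  for (i in (n + 1):(2 * n)) imgs[, , i] <- 0.8 + rnorm(256, 0, 0.02)
  labs <- factor(rep(c("background", "organ"), each = n),
                 levels = c("background", "organ"))
  cfg <- net_config(c(16, 16), epochs = 4, seed = 5)
  net <- train_classifier(build_network(cfg, "X"),
                          list(images = imgs, labels = labs))
  expect_equal(tail(net$log$val_acc, 1), 1)
  pr <- predict_axis(net, imgs)
  expect_equal(mean(pr$label == labs), 1)
  expect_equal(pr$p_background + pr$p_organ, rep(1, 2 * n), tolerance = 1e-6)

  # training is reproducible: same seed, same final weights and loss
  net2 <- train_classifier(build_network(cfg, "X"),
                           list(images = imgs, labels = labs))
  expect_identical(net$par, net2$par)
  expect_identical(net$log$iterations$loss, net2$log$iterations$loss)

  # loss stays finite, weights contain no non-finite values
  expect_true(all(is.finite(net$log$iterations$loss)))
  expect_true(all(vapply(net$par[c("W1", "W2", "Wf")],
                         function(w) all(is.finite(w)), logical(1))))
})

test_that("training rejects degenerate datasets and bad shapes", {
  imgs <- array(runif(16 * 16 * 8), c(16, 16, 8))
  one_class <- factor(rep("organ", 8), levels = c("background", "organ"))
  net <- build_network(net_config(c(16, 16), seed = 1), "X")
  expect_error(train_classifier(net, list(images = imgs, labels = one_class)),
               "both classes")
  expect_error(train_classifier(net, list(images = imgs[, , 0],
                                          labels = one_class[0])),
               "empty")
  expect_error(predict_axis(net, matrix(0, 8, 8)), "does not match")
  # empty batch: empty result
  p <- predict_axis(net, array(0, c(16, 16, 0)))
  expect_identical(nrow(p), 0L)
})
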