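# The three per-axis binary slice classifiers (sagittal/X, coronal/Y,
# axial/Z).  Architecture and training hyperparameters follow the reference
# configuration: two 3x3 convolution blocks with 32 filters, three batch
# normalizations, three ReLUs, two 2x2 max-pools, a 2-unit fully connected
# softmax head; SGD with momentum, lr 0.01, minibatch 64, shuffled every
# epoch.  The numerical core lives in src/cnn.cpp; all randomness
# (initialization, shuffling, splits) is driven by R's RNG so a fixed seed
# reproduces training bit for bit.

#' Network configuration
#'
#' @param input_shape image size `c(rows, cols)`; the canonical shapes are
#'   X: 43x512, Y: 43x256, Z: 512x512.
#' @param n_filters convolution filters per layer (default 32).
#' @param filter_size convolution kernel size; only 3 is supported.
#' @param epochs training epochs; 40 is the final-system setting, 4 the
#'   fast preset (see [axis_net_config()]).
#' @param learning_rate SGDM learning rate (default 0.01).
#' @param minibatch SGD minibatch size (default 64).
#' @param momentum SGDM momentum (default 0.9; conventional value, the
#'   reference configuration does not state one).
#' @param validation_frequency evaluate the held-out split every this many
#'   iterations (default 30).
#' @param shuffle only `"every-epoch"` is supported.
#' @param seed RNG seed for init/shuffling/split.
#' @param class_weighting inverse-frequency loss weights (BC points
#'   outnumber OC); set `FALSE` for unweighted loss.
#' @param val_fraction held-out fraction (default 0.15, stratified).
#' @param l2 L2 weight decay on convolution/fully-connected weights
#'   (default 1e-4, the reference training environment's default; biases
#'   and batch-norm parameters are not decayed).
#' @param bn_momentum running-statistics update rate for batch norm.
#' @param bn_chunk batch-norm sub-batch size; `NULL` picks the largest
#'   memory-safe value (ghost batch norm for large inputs).
#' @return object of class `net_config`.
#' @export
net_config <- function(input_shape, n_filters = 32, filter_size = 3,
                       epochs = 40, learning_rate = 0.01, minibatch = 64,
                       momentum = 0.9, validation_frequency = 30,
                       shuffle = "every-epoch", seed = 1L,
                       class_weighting = TRUE, val_fraction = 0.15,
                       l2 = 1e-4, bn_momentum = 0.1, bn_chunk = NULL) {
  if (length(input_shape) != 2 || any(input_shape < 8))
    stop("input_shape must be c(rows, cols) with both >= 8")
  if (filter_size != 3) stop("only filter_size = 3 is supported")
  stopifnot(n_filters >= 1, epochs >= 1, learning_rate > 0, minibatch >= 1,
            momentum >= 0, momentum < 1, validation_frequency >= 1,
            val_fraction >= 0, val_fraction < 1)
  if (!identical(shuffle, "every-epoch"))
    stop("only shuffle = 'every-epoch' is supported")
  if (is.null(bn_chunk)) {
    npix <- prod(input_shape)
    bn_chunk <- max(1L, min(minibatch,
                            as.integer(floor(6e8 / (npix * n_filters * 8)))))
  }
  structure(list(input_shape = as.integer(input_shape),
                 n_filters = as.integer(n_filters),
                 filter_size = 3L, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 minibatch = as.integer(minibatch), momentum = momentum,
                 validation_frequency = as.integer(validation_frequency),
                 shuffle = shuffle, seed = as.integer(seed),
                 class_weighting = isTRUE(class_weighting),
                 val_fraction = val_fraction, l2 = l2,
                 bn_momentum = bn_momentum,
                 bn_chunk = as.integer(bn_chunk)),
            class = "net_config")
}

#' Canonical per-axis configuration
#'
#' @param axis `"X"`, `"Y"` or `"Z"`.
#' @param preset `"full"` (40 epochs, the final-system setting) or
#'   `"fast"` (4 epochs).
#' @param target_z projection row count for X/Y inputs.
#' @param in_plane in-slice image size (rows, cols) of the axial slices.
#' @param ... passed to [net_config()].
#' @export
axis_net_config <- function(axis = c("X", "Y", "Z"),
                            preset = c("full", "fast"),
                            target_z = 43, in_plane = c(512, 512), ...) {
  axis <- match.arg(axis)
  preset <- match.arg(preset)
  shape <- switch(axis,
                  X = c(target_z, in_plane[2]),
                  Y = c(target_z, in_plane[2] / 2),
                  Z = in_plane)
  net_config(input_shape = shape,
             epochs = if (preset == "fast") 4L else 40L, ...)
}

# layer census of the fixed architecture (for introspection and tests)
net_layer_census <- function() {
  data.frame(layer = c("input", "conv", "batchnorm", "relu", "maxpool",
                       "conv", "batchnorm", "relu", "maxpool",
                       "batchnorm", "relu", "fullyconnected", "softmax",
                       "classification"),
             stringsAsFactors = FALSE)
}

#' Build an untrained per-axis classifier
#'
#' He-normal weight initialization seeded from `cfg$seed`.  Class order is
#' fixed as `(background, organ)`.
#'
#' @param cfg a [net_config()].
#' @param axis which projection this classifier serves.
#' @return object of class `axis_classifier`.
#' @export
build_network <- function(cfg, axis = "X") {
  nf <- cfg$n_filters
  H <- cfg$input_shape[1]; W <- cfg$input_shape[2]
  D <- (H %/% 2 %/% 2) * (W %/% 2 %/% 2) * nf
  set.seed(cfg$seed)
  par <- list(
    H = H, W = W, nf = nf,
    W1 = matrix(rnorm(9 * nf, 0, sqrt(2 / 9)), 9, nf),
    b1 = numeric(nf),
    W2 = matrix(rnorm(9 * nf * nf, 0, sqrt(2 / (9 * nf))), 9 * nf, nf),
    b2 = numeric(nf),
    Wf = matrix(rnorm(D * 2, 0, sqrt(2 / D)), D, 2),
    bf = numeric(2),
    g1 = rep(1, nf), be1 = numeric(nf), rm1 = numeric(nf), rv1 = rep(1, nf),
    g2 = rep(1, nf), be2 = numeric(nf), rm2 = numeric(nf), rv2 = rep(1, nf),
    g3 = rep(1, nf), be3 = numeric(nf), rm3 = numeric(nf), rv3 = rep(1, nf))
  vel <- lapply(par[c("W1", "b1", "W2", "b2", "Wf", "bf",
                      "g1", "be1", "g2", "be2", "g3", "be3")],
                function(p) { p[] <- 0; p })
  structure(list(axis = axis, cfg = cfg, par = par, vel = vel,
                 classes = c("background", "organ"),
                 layers = net_layer_census(),
                 log = NULL, trained = FALSE, type = "cnn"),
            class = "axis_classifier")
}

#' A rule-based stand-in classifier
#'
#' Wraps an arbitrary decision function as an `axis_classifier`, for oracle
#' tests and pipeline plumbing that need deterministic per-axis decisions
#' without training.  `fun(images)` receives an H x W x N array and returns
#' the organ probability per image.
#'
#' @param fun decision function.
#' @param axis projection tag.
#' @export
stub_classifier <- function(fun, axis = "X") {
  structure(list(axis = axis, cfg = NULL, fun = fun,
                 classes = c("background", "organ"),
                 layers = net_layer_census(),
                 log = NULL, trained = TRUE, type = "stub"),
            class = "axis_classifier")
}

#' @export
print.axis_classifier <- function(x, ...) {
  cat(sprintf("<axis_classifier %s (%s)%s>\n", x$axis, x$type,
              if (x$trained) ", trained" else ""))
  invisible(x)
}

# total trainable parameter count
n_params <- function(net) {
  sum(vapply(net$par[c("W1", "b1", "W2", "b2", "Wf", "bf",
                       "g1", "be1", "g2", "be2", "g3", "be3")],
             length, integer(1)))
}

# images argument: H x W matrix or H x W x N array -> array
as_image_batch <- function(images) {
  if (is.matrix(images)) images <- array(images, c(dim(images), 1))
  if (length(dim(images)) != 3) stop("images must be H x W or H x W x N")
  images
}

#' Train a per-axis classifier
#'
#' SGD with momentum on the weighted softmax cross-entropy, shuffling every
#' epoch; an optional stratified held-out split is evaluated after each
#' epoch.  Deterministic for a fixed seed.
#'
#' @param net untrained [build_network()] result.
#' @param dataset `list(images, labels)` (one axis of [build_dataset()]).
#' @param cfg optional config override (defaults to `net$cfg`).
#' @return the trained classifier with a `log` data.frame (per-iteration
#'   loss/accuracy, per-epoch validation accuracy).
#' @export
train_classifier <- function(net, dataset, cfg = NULL) {
  if (net$type != "cnn") stop("only cnn classifiers can be trained")
  if (is.null(cfg)) cfg <- net$cfg
  imgs <- as_image_batch(dataset$images)
  labs <- factor(dataset$labels, levels = net$classes)
  n <- length(labs)
  if (n == 0) stop("training dataset is empty")
  if (dim(imgs)[3] != n) stop("images/labels length mismatch")
  if (length(unique(labs)) < 2)
    stop("training requires both classes to be present")
  y <- as.integer(labs) - 1L                 # 0 = background, 1 = organ

  set.seed(cfg$seed)
  # stratified held-out split
  val_idx <- integer(0)
  if (cfg$val_fraction > 0) {
    for (k in 0:1) {
      idx <- which(y == k)
      nv <- floor(length(idx) * cfg$val_fraction)
      if (nv >= 1 && length(idx) - nv >= 1)
        val_idx <- c(val_idx, sample(idx, nv))
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(unique(y[tr_idx])) < 2)
    stop("training split lost a class; reduce val_fraction")

  cw <- c(1, 1)
  if (cfg$class_weighting) {
    freq <- tabulate(y[tr_idx] + 1L, 2L)
    cw <- sum(freq) / (2 * pmax(freq, 1))
  }

  xtr <- imgs[, , tr_idx, drop = FALSE]
  ytr <- y[tr_idx]
  # keep a sane SGDM update budget on reduced training sets: the reference
  # minibatch (64) against a few dozen images yields a handful of updates
  # per training and the optimization cannot settle; cap the batch so each
  # epoch makes at least ~8 updates (a no-op at the reference data scale)
  mb <- max(1L, min(cfg$minibatch, as.integer(ceiling(length(ytr) / 8))))
  par <- net$par; vel <- net$vel
  log_loss <- numeric(0); log_acc <- numeric(0); log_epoch <- integer(0)
  val_acc <- rep(NA_real_, cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(length(ytr))
    res <- cnn_train_epoch_cpp(par, vel, xtr, ytr, ord,
                               mb, cfg$bn_chunk,
                               cfg$learning_rate, cfg$momentum,
                               cfg$bn_momentum, cw,
                               cfg$l2 %||% 0)
    par <- res$par; vel <- res$vel
    log_loss <- c(log_loss, res$loss)
    log_acc <- c(log_acc, res$acc)
    log_epoch <- c(log_epoch, rep(ep, length(res$loss)))
    if (ep == cfg$epochs) {
      # re-estimate the batch-norm population statistics under the final
      # weights: the running averages lag badly when training converges in
      # a handful of iterations, which breaks inference-mode normalization
      par <- cnn_bn_recalibrate_cpp(par, xtr)
      if (length(val_idx)) {
        pv <- cnn_predict_cpp(par, imgs[, , val_idx, drop = FALSE])
        val_acc[ep] <- mean((pv[, 2] > pv[, 1]) == (y[val_idx] == 1))
      }
    }
  }
  if (any(!is.finite(log_loss)))
    warning("non-finite training loss encountered")
  net$par <- par; net$vel <- vel; net$trained <- TRUE
  net$log <- list(iterations = data.frame(epoch = log_epoch,
                                          loss = log_loss, acc = log_acc),
                  val_acc = val_acc, class_weights = cw,
                  n_train = length(tr_idx), n_val = length(val_idx))
  net
}

#' Classify a batch of projection images
#'
#' @param net a trained `axis_classifier`.
#' @param images H x W matrix or H x W x N array matching the network input.
#' @return data.frame with `label` (factor background/organ, argmax of the
#'   softmax), `p_background`, `p_organ`; rows in batch order.
#' @export
predict_axis <- function(net, images) {
  imgs <- as_image_batch(images)
  nimg <- dim(imgs)[3]
  if (nimg == 0)
    return(data.frame(label = factor(character(0), levels = net$classes),
                      p_background = numeric(0), p_organ = numeric(0)))
  if (net$type == "stub") {
    p1 <- as.numeric(net$fun(imgs))
    probs <- cbind(1 - p1, p1)
  } else {
    if (!all(dim(imgs)[1:2] == net$cfg$input_shape))
      stop("image shape ", paste(dim(imgs)[1:2], collapse = "x"),
           " does not match network input ",
           paste(net$cfg$input_shape, collapse = "x"))
    probs <- cnn_predict_cpp(net$par, imgs)
  }
  lab <- factor(ifelse(probs[, 2] > probs[, 1], "organ", "background"),
                levels = net$classes)
  data.frame(label = lab, p_background = probs[, 1], p_organ = probs[, 2])
}

#' Save / load a classifier checkpoint
#'
#' The weights go to an RDS file with a JSON sidecar recording the axis,
#' class order and configuration hash.
#'
#' @param net an `axis_classifier`.
#' @param path checkpoint path (`.rds`).
#' @export
save_classifier <- function(net, path) {
  saveRDS(net, path)
  sidecar <- list(axis = net$axis, classes = net$classes,
                  trained = net$trained,
                  cfg_hash = if (!is.null(net$cfg)) config_hash(net$cfg) else NA)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "axis_classifier")) stop("not a classifier checkpoint")
  net
}
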