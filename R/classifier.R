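# The 3-D residual patch classifier: architecture presets, seeded training
# with Adam, early stopping on validation loss, and patch-level inference.

#' Model configuration
#'
#' Two presets are provided.  `"resnet50-3d"` is the canonical 50-layer
#' bottleneck residual network with 3-D kernels (stages 3-4-6-3 on 64 base
#' channels).  `"small-3d"` keeps the same bottleneck topology but with two
#' single-block stages on 8 base channels; it is sized so that training and
#' sliding-window inference are practical on one CPU and is the preset used
#' throughout the phantom experiments.
#'
#' @param preset `"resnet50-3d"` (default) or `"small-3d"`.
#' @param base_channels stem width; defaults to 64 or 12 by preset.
#' @param stage_blocks bottleneck blocks per stage; defaults to
#'   `c(3, 4, 6, 3)` or `c(1, 1)` by preset.
#' @param seed integer seed fixing the weight initialisation.
#' @return A [ModelConfig-class].
#' @export
modelConfig <- function(preset = c("resnet50-3d", "small-3d"),
                        base_channels = NULL, stage_blocks = NULL,
                        seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(base_channels))
    base_channels <- if (preset == "small-3d") 12L else 64L
  if (is.null(stage_blocks))
    stage_blocks <- if (preset == "small-3d") c(1L, 1L) else c(3L, 4L, 6L, 3L)
  new("ModelConfig", preset = preset, inputShape = c(32L, 32L, 32L, 1L),
      baseChannels = as.integer(base_channels),
      stageBlocks = as.integer(stage_blocks), seed = as.integer(seed))
}

#' Training configuration
#'
#' Defaults follow the reference recipe: up to 50 epochs of Adam at an
#' initial learning rate of 5e-4 with early stopping on the validation
#' loss.  The patience and batch size are package choices.
#'
#' @param max_epochs epoch cap (default 50).
#' @param learning_rate initial Adam learning rate (default 0.0005).
#' @param patience epochs without validation-loss improvement before
#'   stopping (default 10); must be smaller than `max_epochs`.
#' @param batch_size minibatch size (default 32).
#' @param pos_weight weight multiplier on positive-class loss terms
#'   (default 1); setting it to the training class ratio counteracts the
#'   negative-heavy sampling.
#' @param seed integer seed for shuffling.
#' @return A [TrainConfig-class].
#' @export
trainConfig <- function(max_epochs = 50L, learning_rate = 5e-4,
                        patience = 10L, batch_size = 32L, pos_weight = 1,
                        seed = 1L) {
  new("TrainConfig", maxEpochs = as.integer(max_epochs),
      learningRate = as.numeric(learning_rate),
      patience = as.integer(patience), batchSize = as.integer(batch_size),
      posWeight = as.numeric(pos_weight), seed = as.integer(seed))
}

#' Build an untrained 3-D residual patch classifier
#'
#' Assembles a residual network with 3-D convolutions: a strided stem,
#' max pooling, bottleneck stages per `stageBlocks` (stage `i` works on
#' `baseChannels * 2^(i-1)` bottleneck channels, expansion 4, stride 2 from
#' the second stage on), global average pooling and a single-logit head.
#' Weights are He-initialised deterministically from the config seed.
#'
#' @param config a [ModelConfig-class].
#' @return An untrained network (opaque list) accepted by
#'   [trainClassifier()]; its parameter count is in `$nParams`.
#' @examples
#' net <- buildModel(modelConfig("small-3d"))
#' net$nParams
#' @export
buildModel <- function(config = modelConfig()) {
  validObject(config)
  B <- config@baseChannels
  layers <- list()
  if (config@preset == "resnet50-3d") {
    # canonical stem: strided 7^3 convolution plus overlapping max pooling
    layers <- c(layers, list(nn_conv(1L, B, 7L, 2L, 3L), nn_bn(B), nn_relu(),
                             nn_maxpool(3L, 2L, 1L)))
    stage_strides <- c(1L, rep(2L, length(config@stageBlocks) - 1L))
  } else {
    # CPU-scale stem: an unpadded strided 3^3 convolution and max pooling.
    # Valid (pad-0) convolutions make window evaluations exact crops of a
    # whole-volume evaluation, which sliding-window inference exploits by
    # computing the stem once per ROI (see slideInfer()).
    layers <- c(layers, list(nn_conv(1L, B, 3L, 2L, 0L), nn_bn(B), nn_relu(),
                             nn_maxpool(2L, 2L, 0L)))
    stage_strides <- c(2L, rep(1L, length(config@stageBlocks) - 1L))
  }
  Cin <- B
  for (i in seq_along(config@stageBlocks)) {
    planes <- B * 2L^(i - 1L)
    for (j in seq_len(config@stageBlocks[i])) {
      layers <- c(layers, list(nn_block(Cin, planes,
                                        if (j == 1L) stage_strides[i] else 1L)))
      Cin <- 4L * planes
    }
  }
  layers <- c(layers, list(nn_gap(), nn_dense(Cin)))
  net <- list(layers = layers, inShape = config@inputShape,
              config = config)
  net <- init_net(net, config@seed)
  net$nParams <- tree_count(net_params(net))
  class(net) <- "vv_network"
  net
}

#' @describeIn buildModel parameter count of a network or trained
#'   classifier.
#' @param model a `vv_network` or [TrainedClassifier-class].
#' @export
nParameters <- function(model) {
  if (is(model, "TrainedClassifier")) return(model@net$nParams)
  model$nParams
}

#' Train the patch classifier
#'
#' Minimises binary cross-entropy on a single sigmoid output with Adam.
#' Training stops at `max_epochs` or when the validation loss has not
#' improved for `patience` consecutive epochs; the returned classifier
#' always carries the best-validation-loss weight snapshot.  All
#' randomness (shuffling) derives from the training seed, so training is
#' reproducible end to end on fixed data.
#'
#' @param model an untrained network from [buildModel()].
#' @param train,val [PatchSet-class] objects; both non-empty, and the
#'   training labels must contain both classes.
#' @param config a [TrainConfig-class].
#' @param verbose print one line per epoch.
#' @return A [TrainedClassifier-class] with the per-epoch history.
#' @export
trainClassifier <- function(model, train, val, config = trainConfig(),
                            verbose = FALSE) {
  validObject(config)
  if (!length(train) || !length(val))
    stop("training and validation sets must be non-empty")
  y_tr <- patchLabels(train)
  if (length(unique(y_tr)) < 2L)
    stop("training set contains a single class; need both labels")
  X_tr <- patchVoxels(train)
  X_va <- patchVoxels(val)
  y_va <- patchLabels(val)

  net <- model
  params <- net_params(net)
  state <- adam_init(params)
  hist <- data.frame()
  best <- list(loss = Inf, params = params, layers = net$layers, epoch = 0L)
  wait <- 0L
  n <- length(y_tr)

  for (epoch in seq_len(config@maxEpochs)) {
    idx <- with_seed(child_seed(config@seed, epoch), sample.int(n))
    tr_loss <- 0; tr_correct <- 0
    for (b0 in seq(1L, n, by = config@batchSize)) {
      bi <- idx[b0:min(b0 + config@batchSize - 1L, n)]
      Xb <- X_tr[, bi, drop = FALSE]
      yb <- y_tr[bi]
      fw <- net_forward(net, Xb, training = TRUE)
      net <- fw$net
      tr_loss <- tr_loss + bce_loss(fw$logits, yb, config@posWeight) *
        length(bi)
      tr_correct <- tr_correct + sum((fw$logits > 0) == (yb == 1L))
      grads <- net_backward(net, fw,
                            bce_grad(fw$logits, yb, config@posWeight))
      st <- adam_step(net_params(net), grads, state, config@learningRate)
      state <- st$state
      net <- net_set_params(net, st$params)
    }
    va <- evaluate_net(net, X_va, y_va)
    hist <- rbind(hist, data.frame(
      epoch = epoch, train_loss = tr_loss / n, train_acc = tr_correct / n,
      val_loss = va$loss, val_acc = va$acc))
    if (verbose)
      message(sprintf("epoch %d: train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      epoch, tr_loss / n, tr_correct / n, va$loss, va$acc))
    if (va$loss < best$loss - 1e-9) {
      best <- list(loss = va$loss, params = net_params(net),
                   layers = net$layers, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config@patience) break
    }
  }

  net$layers <- best$layers       # best snapshot incl. batch-norm statistics
  attr(hist, "learning_rate") <- config@learningRate
  attr(hist, "max_epochs") <- config@maxEpochs
  attr(hist, "best_epoch") <- best$epoch
  new("TrainedClassifier", net = unclass(net), history = hist,
      modelConfig = net$config, trainConfig = config)
}

evaluate_net <- function(net, X, y, batch = 256L) {
  n <- length(y)
  loss <- 0; correct <- 0
  for (b0 in seq(1L, n, by = batch)) {
    bi <- b0:min(b0 + batch - 1L, n)
    fw <- net_forward(net, X[, bi, drop = FALSE], training = FALSE,
                      keep_cache = FALSE)
    loss <- loss + bce_loss(fw$logits, y[bi]) * length(bi)
    correct <- correct + sum((fw$logits > 0) == (y[bi] == 1L))
  }
  list(loss = loss / n, acc = correct / n)
}

#' Classify a single 32^3 patch
#'
#' @param classifier a [TrainedClassifier-class].
#' @param patch 32 x 32 x 32 numeric array (or a flattened 32^3 vector).
#' @return Lesion probability in [0, 1]; inference is deterministic.
#' @export
predictPatch <- function(classifier, patch) {
  v <- as.vector(patch)
  if (length(v) != prod(classifier@net$inShape))
    stop("patch must have shape 32 x 32 x 32")
  predictProbs(classifier, matrix(v, ncol = 1L))[1L]
}

#' @describeIn predictPatch probabilities for a matrix of patches (one
#'   flattened patch per column).
#' @param X matrix with `32^3` rows.
#' @param batch internal batch size.
#' @export
predictProbs <- function(classifier, X, batch = 128L) {
  net <- classifier@net
  n <- ncol(X)
  out <- numeric(n)
  for (b0 in seq(1L, n, by = batch)) {
    bi <- b0:min(b0 + batch - 1L, n)
    fw <- net_forward(net, X[, bi, drop = FALSE], training = FALSE,
                      keep_cache = FALSE)
    out[bi] <- stats::plogis(fw$logits)
  }
  out
}

#' @describeIn trainClassifier per-epoch training history.
#' @param classifier a [TrainedClassifier-class].
#' @export
trainingHistory <- function(classifier) classifier@history

setMethod("show", "TrainedClassifier", function(object) {
  h <- object@history
  cat(sprintf("TrainedClassifier (%s, %d parameters)\n",
              object@modelConfig@preset, object@net$nParams))
  if (nrow(h))
    cat(sprintf("  %d epochs (best %d): val loss %.4f, val acc %.3f\n",
                nrow(h), attr(h, "best_epoch"), min(h$val_loss),
                h$val_acc[which.min(h$val_loss)]))
})

#' Save / load a classifier checkpoint
#'
#' The checkpoint carries the weights, both configs and the training
#' history.
#'
#' @param classifier a [TrainedClassifier-class].
#' @param path file path (RDS).
#' @return `saveCheckpoint()` returns `path` invisibly; `loadCheckpoint()`
#'   the restored [TrainedClassifier-class].
#' @export
saveCheckpoint <- function(classifier, path) {
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) readRDS(path)
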