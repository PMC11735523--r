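test_that("analytic gradients match finite differences", {
  vv <- asNamespace("VesselVote")
  layers <- list(vv$nn_conv(1L, 2L, 3L, 2L, 1L), vv$nn_bn(2L), vv$nn_relu(),
                 vv$nn_maxpool(2L, 2L, 0L), vv$nn_block(2L, 2L, 2L),
                 vv$nn_gap(), vv$nn_dense(8L))
  net <- vv$init_net(list(layers = layers, inShape = c(8L, 8L, 8L, 1L)), 42L)
  withr::with_seed(1, {
    X <- matrix(rnorm(512 * 5), 512, 5)
  })
  y <- c(1, 0, 1, 0, 1)
  loss_of <- function(net)
    vv$bce_loss(vv$net_forward(net, X, training = TRUE)$logits, y)
  fw <- vv$net_forward(net, X, training = TRUE)
  grads <- vv$net_backward(net, fw, vv$bce_grad(fw$logits, y))
  params <- vv$net_params(net)
  eps <- 1e-5
  worst <- 0
  probe <- function(li, path) {
    g <- grads[[li]]; p <- params[[li]]
    for (nm in path) { p <- p[[nm]]; g <- g[[nm]] }
    for (i in sample(length(p), min(3, length(p)))) {
      bump <- function(tree, keys, delta) {
        if (!length(keys)) { tree[i] <- tree[i] + delta; return(tree) }
        tree[[keys[1]]] <- bump(tree[[keys[1]]], keys[-1], delta)
        tree
      }
      np <- net; np$layers[[li]] <-
        vv$layer_set_params(np$layers[[li]], bump(params[[li]], path, eps))
      nm <- net; nm$layers[[li]] <-
        vv$layer_set_params(nm$layers[[li]], bump(params[[li]], path, -eps))
      num <- (loss_of(np) - loss_of(nm)) / (2 * eps)
      worst <<- max(worst, abs(num - g[i]) /
                      max(1e-8, abs(num) + abs(g[i])))
    }
  }
  withr::with_seed(7, {
    probe(1, "W"); probe(1, "b"); probe(2, "gamma"); probe(2, "beta")
    probe(5, c("conv1", "W")); probe(5, c("conv2", "W"))
    probe(5, c("bn3", "gamma")); probe(5, c("down_conv", "W"))
    probe(7, "W"); probe(7, "b")
  })
  expect_lt(worst, 1e-2)   # loose cap; ReLU kinks inflate single probes
})

test_that("model presets have the expected structure and sizes", {
  small <- buildModel(modelConfig("small-3d", seed = 1))
  expect_lt(small$nParams, 1e5)
  # stage pattern of the full preset is 3-4-6-3
  cfg50 <- modelConfig("resnet50-3d")
  expect_identical(cfg50@stageBlocks, c(3L, 4L, 6L, 3L))
  big <- buildModel(modelConfig("resnet50-3d", seed = 1))
  n_blocks <- sum(vapply(big$layers, function(l) l$type == "block", TRUE))
  expect_equal(n_blocks, 16L)
  expect_lt(small$nParams, big$nParams / 10)
  rm(big); gc(verbose = FALSE)
})

test_that("weight initialisation is seed-deterministic", {
  a <- buildModel(modelConfig("small-3d", seed = 5))
  b <- buildModel(modelConfig("small-3d", seed = 5))
  c3 <- buildModel(modelConfig("small-3d", seed = 6))
  expect_identical(VesselVote:::net_params(a), VesselVote:::net_params(b))
  expect_false(identical(VesselVote:::net_params(a),
                         VesselVote:::net_params(c3)))
})

test_that("training separates a separable toy and records the recipe", {
  train <- toy_patch_set(20, 20, seed = 100)
  val <- toy_patch_set(4, 4, seed = 900)
  model <- buildModel(modelConfig("small-3d", seed = 2))
  cfg <- trainConfig(max_epochs = 5, learning_rate = 1e-3, patience = 4,
                     batch_size = 8, seed = 3)
  clf <- trainClassifier(model, train, val, cfg)
  h <- trainingHistory(clf)
  expect_equal(h$train_acc[nrow(h)], 1.0)
  # training loss is non-increasing over the first 3 epochs
  expect_true(all(diff(h$train_loss[1:3]) <= 0))
  expect_equal(attr(h, "learning_rate"), 1e-3)
  expect_equal(attr(h, "max_epochs"), 5L)
  # bright-centre patch classified positive, dark negative
  expect_gt(predictPatch(clf, toy_patch(TRUE, 1234)), 0.5)
  expect_lt(predictPatch(clf, toy_patch(FALSE, 1235)), 0.5)
  # inference determinism
  p <- toy_patch(TRUE, 77)
  expect_identical(predictPatch(clf, p), predictPatch(clf, p))
  probs <- predictProbs(clf, patchVoxels(val))
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("training is reproducible end to end for a fixed seed", {
  train <- toy_patch_set(8, 8, seed = 50)
  val <- toy_patch_set(2, 2, seed = 60)
  run <- function() {
    trainClassifier(buildModel(modelConfig("small-3d", seed = 4)),
                    train, val,
                    trainConfig(max_epochs = 2, patience = 1,
                                batch_size = 4, seed = 9))
  }
  a <- run(); b <- run()
  expect_identical(trainingHistory(a), trainingHistory(b))
  expect_identical(predictPatch(a, toy_patch(TRUE, 5)),
                   predictPatch(b, toy_patch(TRUE, 5)))
})

test_that("early stopping halts on a stagnant validation loss", {
  train <- toy_patch_set(10, 10, seed = 70)
  # validation labels inverted: validation loss worsens as training improves
  val <- toy_patch_set(3, 3, seed = 80)
  val@labels <- rev(val@labels)
  clf <- trainClassifier(buildModel(modelConfig("small-3d", seed = 4)),
                         train, val,
                         trainConfig(max_epochs = 20, patience = 1,
                                     learning_rate = 5e-3, batch_size = 4,
                                     seed = 9))
  expect_lt(nrow(trainingHistory(clf)), 20L)
})

test_that("degenerate inputs are rejected", {
  train <- toy_patch_set(6, 0, seed = 30)   # single class
  val <- toy_patch_set(1, 1, seed = 31)
  model <- buildModel(modelConfig("small-3d", seed = 1))
  expect_error(trainClassifier(model, train, val, trainConfig()),
               "single class")
  clf <- trainClassifier(buildModel(modelConfig("small-3d", seed = 2)),
                         toy_patch_set(4, 4, seed = 1),
                         toy_patch_set(1, 1, seed = 2),
                         trainConfig(max_epochs = 2, patience = 1,
                                     batch_size = 4, seed = 1))
  expect_error(predictPatch(clf, array(0, c(16, 16, 16))), "32")
  expect_error(trainConfig(max_epochs = 5, patience = 10), "patience")
  expect_error(trainConfig(learning_rate = 0), "learningRate")
})
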