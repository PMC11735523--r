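# Minimal dense 3-D convolutional network engine backing the patch
# classifier: im2col convolutions (C++), batch normalisation, ReLU, max
# pooling, bottleneck residual blocks, global average pooling and a single
# sigmoid head, with exact analytic gradients and an Adam optimiser.
# Feature maps are matrices with one sample per column, flattened in R
# array order (x, y, z, channel).

nn_conv <- function(Cin, Cout, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  list(type = "conv", W = matrix(0, k^3 * Cin, Cout), b = numeric(Cout),
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad),
       Cin = as.integer(Cin), Cout = as.integer(Cout))
}

nn_bn <- function(C) {
  list(type = "bn", gamma = rep(1, C), beta = rep(0, C), rm = rep(0, C),
       rv = rep(1, C), mom = 0.1, eps = 1e-5, C = as.integer(C))
}

nn_relu <- function() list(type = "relu")

nn_maxpool <- function(k, stride, pad = 0L) {
  list(type = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad))
}

nn_gap <- function() list(type = "gap")

nn_dense <- function(Cin) {
  list(type = "dense", W = matrix(0, 1, Cin), b = 0, Cin = as.integer(Cin))
}

# Bottleneck residual block: 1x1 reduce -> 3x3 (carries the stride) ->
# 1x1 expand (x4), with a projection shortcut when shape changes.
nn_block <- function(Cin, planes, stride = 1L) {
  Cout <- 4L * planes
  down <- NULL
  if (stride != 1L || Cin != Cout)
    down <- list(conv = nn_conv(Cin, Cout, 1L, stride, 0L), bn = nn_bn(Cout))
  list(type = "block",
       conv1 = nn_conv(Cin, planes, 1L, 1L, 0L), bn1 = nn_bn(planes),
       conv2 = nn_conv(planes, planes, 3L, stride, 1L), bn2 = nn_bn(planes),
       conv3 = nn_conv(planes, Cout, 1L, 1L, 0L), bn3 = nn_bn(Cout),
       down = down, Cout = Cout)
}

conv_out_shape <- function(shape, layer) {
  sp <- (shape[1:3] + 2L * layer$pad - layer$k) %/% layer$stride + 1L
  c(sp, if (is.null(layer$Cout)) shape[4] else layer$Cout)
}

# ---- forward ---------------------------------------------------------------

bn_stats <- function(x, S, C) {
  # per-channel mean/var over the S spatial rows of each channel and all
  # columns; rows of x are grouped channel-blocks of length S
  grp <- rep(seq_len(C), each = S)
  M <- S * ncol(x)
  mu <- rowSums(rowsum(x, grp, reorder = FALSE)) / M
  xc <- x - mu[grp]
  v <- rowSums(rowsum(xc * xc, grp, reorder = FALSE)) / M
  list(mu = mu, var = v, grp = grp, M = M)
}

layer_fwd <- function(layer, x, shape, training, keep_cache) {
  cache <- NULL
  switch(layer$type,
    conv = {
      y <- cpp_conv3d_fwd(x, shape, layer$W, layer$b, layer$k, layer$stride,
                          layer$pad)
      shape_out <- conv_out_shape(shape, layer)
      if (keep_cache) cache <- list(x = x, shape = shape)
      list(y = y, shape = shape_out, cache = cache, layer = layer)
    },
    bn = {
      S <- prod(shape[1:3]); C <- shape[4]
      grp <- rep(seq_len(C), each = S)
      if (training) {
        st <- bn_stats(x, S, C)
        ivar <- 1 / sqrt(st$var + layer$eps)
        xhat <- (x - st$mu[grp]) * ivar[grp]
        layer$rm <- (1 - layer$mom) * layer$rm + layer$mom * st$mu
        layer$rv <- (1 - layer$mom) * layer$rv + layer$mom * st$var
        y <- layer$gamma[grp] * xhat + layer$beta[grp]
        if (keep_cache) cache <- list(xhat = xhat, ivar = ivar, grp = grp,
                                      S = S, C = C, M = S * ncol(x))
      } else {
        # inference: fold normalisation and affine into one multiply-add
        a <- layer$gamma / sqrt(layer$rv + layer$eps)
        y <- x * a[grp] + (layer$beta - a * layer$rm)[grp]
      }
      list(y = y, shape = shape, cache = cache, layer = layer)
    },
    relu = {
      y <- pmax(x, 0)
      if (keep_cache) cache <- list(pos = x > 0)
      list(y = y, shape = shape, cache = cache, layer = layer)
    },
    maxpool = {
      r <- cpp_maxpool_fwd(x, shape, layer$k, layer$stride, layer$pad)
      sp <- (shape[1:3] + 2L * layer$pad - layer$k) %/% layer$stride + 1L
      if (keep_cache) cache <- list(argmax = r$argmax, insize = nrow(x))
      list(y = r$y, shape = c(sp, shape[4]), cache = cache, layer = layer)
    },
    gap = {
      S <- prod(shape[1:3]); C <- shape[4]
      grp <- rep(seq_len(C), each = S)
      y <- rowsum(x, grp, reorder = FALSE) / S
      if (keep_cache) cache <- list(S = S, C = C, grp = grp)
      list(y = y, shape = c(1L, 1L, 1L, C), cache = cache, layer = layer)
    },
    dense = {
      y <- as.vector(layer$W %*% x) + layer$b
      if (keep_cache) cache <- list(x = x)
      list(y = y, shape = c(1L, 1L, 1L, 1L), cache = cache, layer = layer)
    },
    block = {
      names_main <- c("conv1", "bn1", "relu", "conv2", "bn2", "relu2",
                      "conv3", "bn3")
      seq_layers <- list(layer$conv1, layer$bn1, nn_relu(), layer$conv2,
                         layer$bn2, nn_relu(), layer$conv3, layer$bn3)
      h <- x; hshape <- shape
      caches <- vector("list", length(seq_layers))
      for (i in seq_along(seq_layers)) {
        r <- layer_fwd(seq_layers[[i]], h, hshape, training, keep_cache)
        h <- r$y; hshape <- r$shape
        caches[[i]] <- r$cache
        seq_layers[[i]] <- r$layer
      }
      layer$conv1 <- seq_layers[[1]]; layer$bn1 <- seq_layers[[2]]
      layer$conv2 <- seq_layers[[4]]; layer$bn2 <- seq_layers[[5]]
      layer$conv3 <- seq_layers[[7]]; layer$bn3 <- seq_layers[[8]]
      if (is.null(layer$down)) {
        s <- x; dcache <- NULL
      } else {
        r1 <- layer_fwd(layer$down$conv, x, shape, training, keep_cache)
        r2 <- layer_fwd(layer$down$bn, r1$y, r1$shape, training, keep_cache)
        layer$down$conv <- r1$layer; layer$down$bn <- r2$layer
        s <- r2$y
        dcache <- list(conv = r1$cache, bn = r2$cache)
      }
      pre <- h + s
      y <- pmax(pre, 0)
      if (keep_cache)
        cache <- list(main = caches, down = dcache, pos = pre > 0,
                      names = names_main)
      list(y = y, shape = hshape, cache = cache, layer = layer)
    },
    stop("unknown layer type: ", layer$type))
}

net_forward <- function(net, X, training = FALSE, keep_cache = training,
                        from_layer = 1L, in_shape = net$inShape) {
  shape <- as.integer(in_shape)
  if (nrow(X) != prod(shape))
    stop("input rows must equal ", prod(shape))
  caches <- vector("list", length(net$layers))
  shapes <- vector("list", length(net$layers))
  x <- X
  for (i in seq(from_layer, length(net$layers))) {
    shapes[[i]] <- shape
    r <- layer_fwd(net$layers[[i]], x, shape, training, keep_cache)
    x <- r$y; shape <- r$shape
    caches[[i]] <- r$cache
    net$layers[[i]] <- r$layer
  }
  list(logits = as.vector(x), caches = caches, shapes = shapes, net = net)
}

# Shared-stem geometry for sliding-window inference.  When the network
# opens with an unpadded conv/bn/relu/maxpool prefix, a window's features
# after that prefix are an exact crop of the whole-volume features; this
# returns the prefix length, its cumulative stride, and the feature-window
# edge length, or NULL when the trick does not apply.
stem_geometry <- function(net, window) {
  l <- net$layers
  if (length(l) < 5L) return(NULL)
  if (l[[1]]$type != "conv" || l[[1]]$pad != 0L) return(NULL)
  if (l[[2]]$type != "bn" || l[[3]]$type != "relu") return(NULL)
  if (l[[4]]$type != "maxpool" || l[[4]]$pad != 0L) return(NULL)
  w1 <- (window - l[[1]]$k) %/% l[[1]]$stride + 1L
  wf <- (w1 - l[[4]]$k) %/% l[[4]]$stride + 1L
  list(n_layers = 4L, stride = l[[1]]$stride * l[[4]]$stride, wf = wf,
       channels = l[[1]]$Cout)
}

# ---- backward --------------------------------------------------------------

chan_sum <- function(x, grp) rowSums(rowsum(x, grp, reorder = FALSE))

layer_bwd <- function(layer, cache, dy, shape_in) {
  switch(layer$type,
    conv = {
      r <- cpp_conv3d_bwd(cache$x, dy, cache$shape, layer$W, layer$k,
                          layer$stride, layer$pad)
      list(dx = r$dx, g = list(W = r$dW, b = as.vector(r$db)))
    },
    bn = {
      grp <- cache$grp
      dxhat <- dy * layer$gamma[grp]
      s1 <- chan_sum(dxhat, grp)
      s2 <- chan_sum(dxhat * cache$xhat, grp)
      dx <- cache$ivar[grp] *
        (dxhat - (s1[grp] + cache$xhat * s2[grp]) / cache$M)
      list(dx = dx,
           g = list(gamma = chan_sum(dy * cache$xhat, grp),
                    beta = chan_sum(dy, grp)))
    },
    relu = list(dx = dy * cache$pos, g = NULL),
    maxpool = list(dx = cpp_maxpool_bwd(dy, cache$argmax, cache$insize),
                   g = NULL),
    gap = list(dx = dy[cache$grp, , drop = FALSE] / cache$S, g = NULL),
    dense = {
      dyr <- matrix(dy, 1L)
      list(dx = crossprod(layer$W, dyr),
           g = list(W = dyr %*% t(cache$x), b = sum(dy)))
    },
    block = {
      dpre <- dy * cache$pos
      seq_layers <- list(layer$conv1, layer$bn1, nn_relu(), layer$conv2,
                         layer$bn2, nn_relu(), layer$conv3, layer$bn3)
      g <- list()
      d <- dpre
      for (i in rev(seq_along(seq_layers))) {
        r <- layer_bwd(seq_layers[[i]], cache$main[[i]], d, NULL)
        d <- r$dx
        if (!is.null(r$g)) g[[cache$names[i]]] <- r$g
      }
      if (is.null(layer$down)) {
        d <- d + dpre
      } else {
        rb <- layer_bwd(layer$down$bn, cache$down$bn, dpre, NULL)
        rc <- layer_bwd(layer$down$conv, cache$down$conv, rb$dx, NULL)
        g$down_bn <- rb$g
        g$down_conv <- rc$g
        d <- d + rc$dx
      }
      list(dx = d, g = g)
    },
    stop("unknown layer type"))
}

net_backward <- function(net, fw, dlogits) {
  n <- length(net$layers)
  grads <- vector("list", n)
  d <- matrix(dlogits, 1L)
  for (i in rev(seq_len(n))) {
    r <- layer_bwd(net$layers[[i]], fw$caches[[i]], d, fw$shapes[[i]])
    grads[i] <- list(r$g)
    d <- r$dx
  }
  grads
}

# ---- parameters ------------------------------------------------------------

PARAM_KEYS <- c("W", "b", "gamma", "beta")

layer_params <- function(layer) {
  switch(layer$type,
    conv = , dense = list(W = layer$W, b = layer$b),
    bn = list(gamma = layer$gamma, beta = layer$beta),
    block = {
      p <- list(conv1 = layer_params(layer$conv1),
                bn1 = layer_params(layer$bn1),
                conv2 = layer_params(layer$conv2),
                bn2 = layer_params(layer$bn2),
                conv3 = layer_params(layer$conv3),
                bn3 = layer_params(layer$bn3))
      if (!is.null(layer$down)) {
        p$down_conv <- layer_params(layer$down$conv)
        p$down_bn <- layer_params(layer$down$bn)
      }
      p
    },
    NULL)
}

layer_set_params <- function(layer, p) {
  switch(layer$type,
    conv = , dense = { layer$W <- p$W; layer$b <- p$b; layer },
    bn = { layer$gamma <- p$gamma; layer$beta <- p$beta; layer },
    block = {
      layer$conv1 <- layer_set_params(layer$conv1, p$conv1)
      layer$bn1 <- layer_set_params(layer$bn1, p$bn1)
      layer$conv2 <- layer_set_params(layer$conv2, p$conv2)
      layer$bn2 <- layer_set_params(layer$bn2, p$bn2)
      layer$conv3 <- layer_set_params(layer$conv3, p$conv3)
      layer$bn3 <- layer_set_params(layer$bn3, p$bn3)
      if (!is.null(layer$down)) {
        layer$down$conv <- layer_set_params(layer$down$conv, p$down_conv)
        layer$down$bn <- layer_set_params(layer$down$bn, p$down_bn)
      }
      layer
    },
    layer)
}

net_params <- function(net) lapply(net$layers, layer_params)

net_set_params <- function(net, params) {
  for (i in seq_along(net$layers))
    if (!is.null(params[[i]]))
      net$layers[[i]] <- layer_set_params(net$layers[[i]], params[[i]])
  net
}

tree_map <- function(f, x) {
  if (is.numeric(x)) return(f(x))
  if (is.null(x)) return(NULL)
  lapply(x, function(e) tree_map(f, e))
}

tree_map2 <- function(f, a, b) {
  if (is.numeric(a)) return(f(a, b))
  if (is.null(a)) return(NULL)
  out <- vector("list", length(a))
  nm <- names(a)
  names(out) <- nm
  for (i in seq_along(a)) {
    bi <- if (!is.null(nm) && nzchar(nm[i])) b[[nm[i]]] else b[[i]]
    out[[i]] <- tree_map2(f, a[[i]], bi)
  }
  out
}

tree_count <- function(x) {
  if (is.numeric(x)) return(length(x))
  if (is.null(x)) return(0L)
  sum(vapply(x, tree_count, 0))
}

# He-normal initialisation of all conv/dense weights; deterministic in seed.
init_net <- function(net, seed) {
  init_layer <- function(layer) {
    if (layer$type %in% c("conv", "dense")) {
      fan_in <- if (layer$type == "conv") nrow(layer$W) else ncol(layer$W)
      layer$W[] <- stats::rnorm(length(layer$W)) * sqrt(2 / fan_in)
      layer$b[] <- 0
    } else if (layer$type == "block") {
      layer$conv1 <- init_layer(layer$conv1)
      layer$conv2 <- init_layer(layer$conv2)
      layer$conv3 <- init_layer(layer$conv3)
      if (!is.null(layer$down)) layer$down$conv <- init_layer(layer$down$conv)
    }
    layer
  }
  with_seed(seed, {
    for (i in seq_along(net$layers))
      net$layers[[i]] <- init_layer(net$layers[[i]])
  })
  net
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

# Numerically stable binary cross-entropy and its gradient wrt logits.
# pos_weight > 1 upweights the positive class (weights w = 1 + (pw-1) y,
# normalised to keep the loss scale comparable across batches).
bce_loss <- function(logits, y, pos_weight = 1) {
  w <- 1 + (pos_weight - 1) * y
  sum(w * ((1 - y) * logits + log1p(exp(-abs(logits))) +
             pmax(-logits, 0))) / sum(w)
}

bce_grad <- function(logits, y, pos_weight = 1) {
  w <- 1 + (pos_weight - 1) * y
  w * (stats::plogis(logits) - y) / sum(w)
}
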