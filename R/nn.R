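# Minimal CNN engine: conv / batch-norm / ReLU / global-average-pool /
# linear layers with SGD-momentum training. Tensors are R arrays with dims
# (H, W, C, N); convolution runs as im2col (C++) + GEMM (BLAS). The engine is
# deliberately small: exactly the pieces the two pipeline models need,
# gradient-checked against numerical derivatives in the test suite.

nn_conv <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L) {
  list(type = "conv", cin = cin, cout = cout, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad),
       W = matrix(stats::rnorm(cout * k * k * cin, 0, sqrt(2 / (k * k * cin))),
                  cout, k * k * cin),
       b = numeric(cout))
}

nn_bn <- function(c, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", c = c, eps = eps, momentum = momentum,
       gamma = rep(1, c), beta = numeric(c),
       running_mean = numeric(c), running_var = rep(1, c))
}

nn_relu <- function() list(type = "relu")
nn_gap <- function() list(type = "gap")

nn_linear <- function(cin, cout) {
  list(type = "linear", cin = cin, cout = cout,
       W = matrix(stats::rnorm(cout * cin, 0, sqrt(2 / cin)), cout, cin),
       b = numeric(cout))
}

nn_resblock <- function(width, k = 3L) {
  # conv-BN-ReLU-conv-BN + identity, ReLU after the addition. The last BN
  # gain starts at zero so every block is initially the identity — without
  # this, deep stacks (16 blocks) start with inflated activations and SGD
  # stalls at the stated learning rate.
  bn2 <- nn_bn(width)
  bn2$gamma <- rep(0, width)
  list(type = "resblock",
       layers = list(nn_conv(width, width, k), nn_bn(width), nn_relu(),
                     nn_conv(width, width, k), bn2))
}

# ---- forward/backward primitives -------------------------------------------

conv_fw <- function(layer, x) {
  y <- cpp_conv_fw(x, layer$W, layer$b, layer$k, layer$stride, layer$pad)
  list(out = y, cache = list(x = x))
}

conv_bw <- function(layer, cache, dy) {
  r <- cpp_conv_bw(cache$x, layer$W, dy, layer$k, layer$stride, layer$pad)
  list(dx = r$dx, grads = list(W = r$dW, b = r$db))
}

# per-channel helpers on (H,W,C,N) tensors without transposition: a length-C
# vector expanded with rep(v, each = H*W) recycles correctly over N
ch_expand <- function(v, d) rep(v, each = d[1] * d[2])

# per-channel means of a (H,W,C,N) tensor
ch_means <- function(x, d) {
  rowMeans(matrix(colMeans(matrix(x, d[1] * d[2])), d[3], d[4]))
}

bn_fw <- function(layer, x, training) {
  d <- dim(x)
  if (training) {
    mu <- ch_means(x, d)
    xc <- x - ch_expand(mu, d)
    va <- ch_means(xc * xc, d)
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
      layer$momentum * mu
    layer$running_var <- (1 - layer$momentum) * layer$running_var +
      layer$momentum * va
  } else {
    mu <- layer$running_mean
    xc <- x - ch_expand(mu, d)
    va <- layer$running_var
  }
  inv_sd <- 1 / sqrt(va + layer$eps)
  xhat <- xc * ch_expand(inv_sd, d)
  y <- xhat * ch_expand(layer$gamma, d) + ch_expand(layer$beta, d)
  list(out = y, layer = layer,
       cache = list(xhat = xhat, inv_sd = inv_sd, d = d, training = training))
}

bn_bw <- function(layer, cache, dy) {
  d <- cache$d
  dgamma <- ch_means(dy * cache$xhat, d) * (d[1] * d[2] * d[4])
  dbeta <- ch_means(dy, d) * (d[1] * d[2] * d[4])
  dxhat <- dy * ch_expand(layer$gamma, d)
  if (cache$training) {
    m1 <- ch_means(dxhat, d)
    m2 <- ch_means(dxhat * cache$xhat, d)
    dx <- (dxhat - ch_expand(m1, d) - cache$xhat * ch_expand(m2, d)) *
      ch_expand(cache$inv_sd, d)
  } else {
    dx <- dxhat * ch_expand(cache$inv_sd, d)
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

relu_fw <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bw <- function(cache, dy) dy * cache

gap_fw <- function(x) {
  d <- dim(x)
  y <- matrix(colMeans(matrix(x, nrow = d[1] * d[2])), d[3], d[4])
  list(out = y, cache = d)
}
gap_bw <- function(cache, dy) {
  d <- cache
  array(rep(as.numeric(dy), each = d[1] * d[2]) / (d[1] * d[2]), d)
}

linear_fw <- function(layer, x) {
  list(out = layer$W %*% x + layer$b, cache = x)
}
linear_bw <- function(layer, cache, dy) {
  list(dx = crossprod(layer$W, dy),
       grads = list(W = tcrossprod(dy, cache), b = rowSums(dy)))
}

# ---- network-level forward/backward ----------------------------------------

# forward through a list of layers; returns output, per-layer caches and the
# (possibly updated, via BN running stats) layers
net_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    r <- switch(l$type,
      conv = conv_fw(l, x),
      bn = bn_fw(l, x, training),
      relu = relu_fw(x),
      gap = gap_fw(x),
      linear = linear_fw(l, x),
      resblock = {
        sub <- net_forward(l$layers, x, training)
        pre <- sub$out + x                      # identity skip
        act <- relu_fw(pre)
        layers[[i]]$layers <- sub$layers
        list(out = act$out,
             cache = list(sub = sub$caches, mask = act$cache))
      },
      stop("unknown layer type ", l$type))
    if (l$type == "bn") layers[[i]] <- r$layer
    caches[[i]] <- r$cache
    x <- r$out
  }
  list(out = x, caches = caches, layers = layers)
}

# backward pass; returns input gradient and per-layer grads (NULL for
# parameter-free layers)
net_backward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$type == "conv") {
      r <- conv_bw(l, caches[[i]], dy)
      grads[[i]] <- r$grads; dy <- r$dx
    } else if (l$type == "bn") {
      r <- bn_bw(l, caches[[i]], dy)
      grads[[i]] <- r$grads; dy <- r$dx
    } else if (l$type == "relu") {
      dy <- relu_bw(caches[[i]], dy)
    } else if (l$type == "gap") {
      dy <- gap_bw(caches[[i]], dy)
    } else if (l$type == "linear") {
      r <- linear_bw(l, caches[[i]], dy)
      grads[[i]] <- r$grads; dy <- r$dx
    } else if (l$type == "resblock") {
      dpre <- relu_bw(caches[[i]]$mask, dy)
      r <- net_backward(l$layers, caches[[i]]$sub, dpre)
      grads[[i]] <- r$grads
      dy <- r$dx + dpre                          # skip path
    }
  }
  list(dx = dy, grads = grads)
}

#' Class-weighted softmax cross-entropy
#'
#' Loss for the grade-group classifier: per-sample negative log-likelihoods
#' weighted by the reference class's weight and normalized by the total
#' weight of the batch. With all weights equal to 1 this reduces exactly
#' (bit for bit) to the unweighted mean cross-entropy.
#'
#' @param logits `K x N` matrix of unnormalized scores.
#' @param labels Integer vector of reference classes in `1..K`.
#' @param weights Length-`K` non-negative class weights.
#' @return List with `loss` (scalar), `dlogits` (`K x N`), `probs` (`K x N`
#'   softmax probabilities).
#' @export
weighted_cross_entropy <- function(logits, labels,
                                   weights = rep(1, nrow(logits))) {
  K <- nrow(logits); N <- ncol(logits)
  stopifnot(length(labels) == N, length(weights) == K)
  z <- sweep(logits, 2, apply(logits, 2, max))
  ez <- exp(z)
  p <- sweep(ez, 2, colSums(ez), "/")
  idx <- cbind(labels, seq_len(N))
  w <- weights[labels]
  nll <- -log(p[cbind(labels, seq_len(N))])
  loss <- sum(w * nll) / sum(w)
  onehot <- matrix(0, K, N)
  onehot[idx] <- 1
  dlogits <- sweep(p - onehot, 2, w / sum(w), "*")
  list(loss = loss, dlogits = dlogits, probs = p)
}

# ---- SGD with momentum and weight decay ------------------------------------

sgd_init <- function(layers) {
  lapply(layers, function(l) {
    switch(l$type,
      conv = list(W = l$W * 0, b = l$b * 0),
      linear = list(W = l$W * 0, b = l$b * 0),
      bn = list(gamma = l$gamma * 0, beta = l$beta * 0),
      resblock = sgd_init(l$layers),
      NULL)
  })
}

# one SGD step; decay is the L2 weight decay applied to conv/linear weights
# (not to BN affine parameters or biases, the usual convention)
sgd_step <- function(layers, grads, state, lr, momentum = 0.9, decay = 1e-5) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    g <- grads[[i]]
    if (is.null(g)) next
    if (l$type == "resblock") {
      r <- sgd_step(l$layers, g, state[[i]], lr, momentum, decay)
      layers[[i]]$layers <- r$layers
      state[[i]] <- r$state
      next
    }
    for (p in names(g)) {
      gd <- g[[p]]
      if (p == "W") gd <- gd + decay * l[[p]]
      state[[i]][[p]] <- momentum * state[[i]][[p]] - lr * gd
      layers[[i]][[p]] <- l[[p]] + state[[i]][[p]]
    }
  }
  list(layers = layers, state = state)
}

# step learning-rate schedule: lr0 * factor^floor((epoch-1)/step)
lr_at_epoch <- function(epoch, lr0, step, factor = 0.1) {
  lr0 * factor^((epoch - 1) %/% step)
}
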