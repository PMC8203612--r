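# numerical gradient of the loss w.r.t. one parameter entry
num_grad <- function(layers, x, labels, wts, i, p, k, sub = NULL, eps = 1e-6) {
  tweak <- function(delta) {
    l2 <- layers
    if (is.null(sub)) l2[[i]][[p]][k] <- l2[[i]][[p]][k] + delta
    else l2[[i]]$layers[[sub]][[p]][k] <- l2[[i]]$layers[[sub]][[p]][k] + delta
    f <- gleasonmil:::net_forward(l2, x, training = TRUE)
    weighted_cross_entropy(f$out, labels, wts)$loss
  }
  (tweak(eps) - tweak(-eps)) / (2 * eps)
}

test_that("analytic gradients match numerical derivatives", {
  withr::with_seed(41, {
    layers <- list(gleasonmil:::nn_conv(2, 3, 3, stride = 2),
                   gleasonmil:::nn_bn(3), gleasonmil:::nn_relu(),
                   gleasonmil:::nn_conv(3, 4, 3), gleasonmil:::nn_gap(),
                   gleasonmil:::nn_linear(4, 3))
    x <- array(stats::rnorm(6 * 6 * 2 * 4), c(6, 6, 2, 4))
    labels <- c(1, 2, 3, 1)
    wts <- c(1, 1.5, 0.7)
    f <- gleasonmil:::net_forward(layers, x, training = TRUE)
    ce <- weighted_cross_entropy(f$out, labels, wts)
    bk <- gleasonmil:::net_backward(f$layers, f$caches, ce$dlogits)
    for (i in c(1, 2, 4, 6)) {
      for (p in names(bk$grads[[i]])) {
        g <- bk$grads[[i]][[p]]
        for (k in sample(length(g), min(4, length(g)))) {
          expect_equal(g[k], num_grad(layers, x, labels, wts, i, p, k),
                       tolerance = 1e-4)
        }
      }
    }
    # input gradient
    for (k in sample(length(x), 5)) {
      x2 <- x; x2[k] <- x2[k] + 1e-6
      x3 <- x; x3[k] <- x3[k] - 1e-6
      up <- weighted_cross_entropy(
        gleasonmil:::net_forward(layers, x2, TRUE)$out, labels, wts)$loss
      dn <- weighted_cross_entropy(
        gleasonmil:::net_forward(layers, x3, TRUE)$out, labels, wts)$loss
      expect_equal(bk$dx[k], (up - dn) / 2e-6, tolerance = 1e-4)
    }
  })
})

test_that("residual block gradients include the skip path", {
  withr::with_seed(42, {
    layers <- list(gleasonmil:::nn_conv(2, 4, 1, pad = 0),
                   gleasonmil:::nn_resblock(4), gleasonmil:::nn_gap(),
                   gleasonmil:::nn_linear(4, 2))
    x <- array(stats::rnorm(5 * 5 * 2 * 3), c(5, 5, 2, 3))
    labels <- c(1, 2, 1)
    f <- gleasonmil:::net_forward(layers, x, training = TRUE)
    ce <- weighted_cross_entropy(f$out, labels)
    bk <- gleasonmil:::net_backward(f$layers, f$caches, ce$dlogits)
    for (sub in c(1, 2, 4, 5)) {
      for (p in names(bk$grads[[2]][[sub]])) {
        g <- bk$grads[[2]][[sub]][[p]]
        k <- sample(length(g), 1)
        expect_equal(g[k],
                     num_grad(layers, x, labels, rep(1, 2), 2, p, k, sub = sub),
                     tolerance = 1e-4)
      }
    }
  })
})

test_that("uniform class weights reduce the loss to plain cross-entropy", {
  withr::with_seed(43, {
    logits <- matrix(stats::rnorm(6 * 16), 6, 16)
    labels <- sample(1:6, 16, replace = TRUE)
    ce_w <- weighted_cross_entropy(logits, labels, rep(1, 6))
    nll <- -log(ce_w$probs[cbind(labels, 1:16)])
    expect_identical(ce_w$loss, sum(nll) / 16) # bit-for-bit
    # and the stated weights change the loss
    ce_s <- weighted_cross_entropy(logits, labels, c(1, 1, 1.5, 1.4, 1.7, 1.6))
    expect_false(identical(ce_w$loss, ce_s$loss))
    expect_equal(colSums(ce_w$probs), rep(1, 16), tolerance = 1e-12)
  })
})

test_that("SGD applies momentum, learning rate and weight decay as stated", {
  layers <- list(gleasonmil:::nn_linear(2, 2))
  layers[[1]]$W <- matrix(c(1, 2, 3, 4), 2)
  layers[[1]]$b <- c(0, 0)
  state <- gleasonmil:::sgd_init(layers)
  g <- list(list(W = matrix(1, 2, 2), b = c(1, 1)))
  up <- gleasonmil:::sgd_step(layers, g, state, lr = 0.1, momentum = 0.9,
                              decay = 0.01)
  # v = -lr * (g + decay * W); biases are not decayed
  expect_equal(up$layers[[1]]$W,
               matrix(c(1, 2, 3, 4), 2) - 0.1 * (1 + 0.01 * matrix(c(1, 2, 3, 4), 2)))
  expect_equal(up$layers[[1]]$b, c(-0.1, -0.1))
  up2 <- gleasonmil:::sgd_step(up$layers, g, up$state, lr = 0.1,
                               momentum = 0.9, decay = 0)
  # second step gains the momentum term
  expect_equal(up2$layers[[1]]$b - up$layers[[1]]$b,
               0.9 * c(-0.1, -0.1) - 0.1 * c(1, 1))
})

test_that("step schedule decays by the factor at the stated interval", {
  expect_equal(gleasonmil:::lr_at_epoch(1, 0.01, 25), 0.01)
  expect_equal(gleasonmil:::lr_at_epoch(25, 0.01, 25), 0.01)
  expect_equal(gleasonmil:::lr_at_epoch(26, 0.01, 25), 0.001)
  expect_equal(gleasonmil:::lr_at_epoch(90, 0.1, 40), 0.1 * 0.01)
})

test_that("evaluation-mode forward is a pure function", {
  withr::with_seed(44, {
    layers <- list(gleasonmil:::nn_conv(3, 4, 3, stride = 2),
                   gleasonmil:::nn_bn(4), gleasonmil:::nn_relu(),
                   gleasonmil:::nn_gap(), gleasonmil:::nn_linear(4, 2))
    x <- array(stats::runif(8 * 8 * 3 * 2), c(8, 8, 3, 2))
    o1 <- gleasonmil:::net_forward(layers, x, training = FALSE)$out
    o2 <- gleasonmil:::net_forward(layers, x, training = FALSE)$out
    expect_identical(o1, o2)
  })
})
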