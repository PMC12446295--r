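# The compiled/GEMM paths are verified against naive oracles and central
# finite differences on small tensors.

test_that("conv forward matches the naive direct convolution oracle", {
  withr::with_seed(4, {
    x <- array(rnorm(3 * 9 * 9 * 2), c(3, 9, 9, 2))
    for (spec in list(c(k = 3, s = 1, p = 1), c(k = 3, s = 2, p = 1),
                      c(k = 5, s = 2, p = 2), c(k = 1, s = 1, p = 0))) {
      w <- array(rnorm(4 * 3 * spec["k"] * spec["k"]),
                 c(4, 3, spec["k"], spec["k"]))
      got <- tailkd:::conv_fwd(x, w, spec["s"], spec["p"])
      expect_equal(got, naive_conv(x, w, spec["s"], spec["p"]),
                   tolerance = 1e-10)
    }
  })
})

test_that("conv backward matches finite differences of a scalar loss", {
  withr::with_seed(5, {
    x <- array(rnorm(2 * 6 * 6), c(2, 6, 6, 1))
    w <- array(rnorm(3 * 2 * 3 * 3) * 0.3, c(3, 2, 3, 3))
    loss <- function(xx, ww) sum(sin(tailkd:::conv_fwd(xx, ww, 2, 1)))
    y <- tailkd:::conv_fwd(x, w, 2, 1)
    g <- tailkd:::conv_bwd(x, w, 2, 1, cos(y))
    for (rep in 1:6) {
      i <- sample(length(w), 1)
      expect_lt(fd_rel_error(function(v) { w2 <- w; w2[i] <- v[i]
        loss(x, w2) }, w, g$dW, i), 1e-5)
      j <- sample(length(x), 1)
      expect_lt(fd_rel_error(function(v) { x2 <- x; x2[j] <- v[j]
        loss(x2, w) }, x, g$dx, j), 1e-5)
    }
  })
})

test_that("depthwise conv and avgpool agree with their definitions", {
  withr::with_seed(6, {
    x <- array(rnorm(2 * 6 * 6), c(2, 6, 6, 1))
    w <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
    y <- tailkd:::dwconv_fwd(x, w, 1, 1)
    # depthwise = per-channel full conv with a diagonal kernel
    for (c in 1:2) {
      wfull <- array(0, c(1, 1, 3, 3)); wfull[1, 1, , ] <- w[c, , ]
      expect_equal(array(y[c, , , ], c(1, 6, 6, 1)),
                   naive_conv(array(x[c, , , ], c(1, 6, 6, 1)), wfull, 1, 1),
                   tolerance = 1e-10)
    }
    # avgpool via constant depthwise kernel: a constant input stays constant
    # away from zero-padded borders
    xc <- array(1, c(3, 8, 8, 2))
    wp <- array(1 / 9, c(3, 3, 3))
    p <- tailkd:::dwconv_fwd(xc, wp, 2, 1)
    expect_equal(dim(p), c(3, 4, 4, 2))
    expect_equal(p[1, 2, 2, 1], 1)            # interior: true mean
    expect_equal(p[1, 1, 1, 1], 4 / 9)        # corner: zero padding included
  })
})

test_that("batch norm, layer norm and attention gradients are exact", {
  withr::with_seed(7, {
    # batch norm (training mode)
    x <- array(rnorm(3 * 4 * 4 * 2), c(3, 4, 4, 2))
    gamma <- runif(3, 0.5, 1.5); beta <- rnorm(3)
    fwd <- function(xx) {
      tailkd:::bn_fwd(xx, gamma, beta, numeric(3), rep(1, 3), TRUE)$y
    }
    r <- tailkd:::bn_fwd(x, gamma, beta, numeric(3), rep(1, 3), TRUE)
    g <- tailkd:::bn_bwd(r$cache, gamma, cos(r$y))
    for (rep in 1:5) {
      i <- sample(length(x), 1)
      expect_lt(fd_rel_error(function(v) { x2 <- x; x2[i] <- v[i]
        sum(sin(fwd(x2))) }, x, g$dx, i), 1e-4)
    }
    # layer norm
    xm <- matrix(rnorm(6 * 5), 6, 5)
    lg <- runif(6, 0.5, 1.5); lb <- rnorm(6)
    lr <- tailkd:::ln_fwd(xm, lg, lb)
    lgrad <- tailkd:::ln_bwd(lr$cache, lg, cos(lr$y))
    for (rep in 1:5) {
      i <- sample(length(xm), 1)
      expect_lt(fd_rel_error(function(v) { x2 <- xm; x2[i] <- v[i]
        sum(sin(tailkd:::ln_fwd(x2, lg, lb)$y)) }, xm, lgrad$dx, i), 1e-4)
    }
    # multi-head attention
    d <- 8; L <- 5; B <- 2; heads <- 2
    xa <- array(rnorm(d * L * B), c(d, L, B))
    Wqkv <- matrix(rnorm(3 * d * d, 0, 0.3), 3 * d, d); bqkv <- rnorm(3 * d)
    Wo <- matrix(rnorm(d * d, 0, 0.3), d, d); bo <- rnorm(d)
    att <- function(xx) tailkd:::mhsa_fwd(xx, Wqkv, bqkv, Wo, bo, heads)$y
    fwd <- tailkd:::mhsa_fwd(xa, Wqkv, bqkv, Wo, bo, heads)
    bwd <- tailkd:::mhsa_bwd(fwd$cache, Wqkv, Wo, heads, cos(fwd$y))
    for (rep in 1:5) {
      i <- sample(length(xa), 1)
      expect_lt(fd_rel_error(function(v) { x2 <- xa; x2[i] <- v[i]
        sum(sin(att(x2))) }, xa, bwd$dx, i), 1e-4)
    }
  })
})

test_that("unfold/fold are mutually inverse permutations", {
  withr::with_seed(8, {
    x <- array(rnorm(5 * 8 * 6 * 2), c(5, 8, 6, 2))
    u <- tailkd:::unfold_patches(x, 2)
    expect_equal(dim(u), c(5, 4 * 3, 4 * 2))
    expect_equal(tailkd:::fold_patches(u, 2, 8, 6, 2), x)
    expect_equal(sort(as.vector(u)), sort(as.vector(x)))
  })
})

test_that("whole-network backprop matches central finite differences", {
  withr::with_seed(9, {
    m <- build_student(3, variant = "test-tiny", seed = 21)
    x <- array(rnorm(3 * 64 * 64 * 2), c(3, 64, 64, 2))
    y <- c(1L, 3L)
    fw <- tailkd:::net_forward(m, x, training = TRUE, want_cache = TRUE)
    gl <- tailkd:::ce_loss_grad(fw$logits, y)
    tailkd:::zero_grads(m)
    tailkd:::net_backward(m, fw$caches, gl$dlogits)
    loss_at <- function(id, i, eps) {
      old <- m$params[[id]]
      p <- old; p[i] <- p[i] + eps
      m$params[[id]] <- p
      snap <- as.list(m$buffers)
      l <- tailkd:::ce_loss_grad(
        tailkd:::net_forward(m, x, training = TRUE)$logits, y)$loss
      m$params[[id]] <- old
      for (nm in names(snap)) m$buffers[[nm]] <- snap[[nm]]
      l
    }
    ids <- sample(ls(m$params), 10)
    for (id in ids) {
      i <- sample(length(m$params[[id]]), 1)
      g <- m$grads[[id]][i]
      fd <- (loss_at(id, i, 1e-4) - loss_at(id, i, -1e-4)) / 2e-4
      rel <- abs(g - fd) / max(abs(fd), abs(g), 1e-8)
      expect_lt(rel, 1e-3, label = sprintf("gradient of %s", id))
    }
  })
})
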