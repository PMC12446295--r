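# Primitive tensor operations with exact backward passes.
#
# Layout convention: activations are numeric arrays dim c(C, H, W, N)
# (channel fastest), so per-channel statistics and broadcasts recycle
# naturally over the first dimension, and the im2col GEMM reshapes into
# the next layer's input without permutation. Token matrices inside
# transformer blocks are d x T with one token per column.

conv_out_side <- function(side, k, stride, pad) (side + 2L * pad - k) %/% stride + 1L

is_pointwise <- function(wd, stride, pad) {
  wd[3] == 1 && wd[4] == 1 && stride == 1 && pad == 0
}

# Returns the output and, for patch-extracting kernels, the im2col matrix
# so the backward pass can reuse it.
conv_fwd_full <- function(x, w, stride, pad) {
  d <- dim(x); wd <- dim(w)
  stopifnot(d[1] == wd[2])
  if (is_pointwise(wd, stride, pad)) {
    # 1x1 conv: plain channel mixing, no patch extraction needed
    xm <- x; dim(xm) <- c(d[1], d[2] * d[3] * d[4])
    y <- matrix(w, nrow = wd[1]) %*% xm
    cols <- NULL
  } else {
    cols <- .im2col_cpp(x, d[1], d[2], d[3], d[4], wd[3], wd[4], stride, pad)
    y <- matrix(w, nrow = wd[1]) %*% cols
  }
  dim(y) <- c(wd[1], conv_out_side(d[2], wd[3], stride, pad),
              conv_out_side(d[3], wd[4], stride, pad), d[4])
  list(y = y, cols = cols)
}

conv_fwd <- function(x, w, stride, pad) conv_fwd_full(x, w, stride, pad)$y

conv_bwd <- function(x, w, stride, pad, dy, cols = NULL) {
  d <- dim(x); wd <- dim(w)
  dym <- dy; dim(dym) <- c(wd[1], length(dy) / wd[1])
  if (is_pointwise(wd, stride, pad)) {
    xm <- x; dim(xm) <- c(d[1], d[2] * d[3] * d[4])
    dW <- tcrossprod(dym, xm)
    dim(dW) <- wd
    dx <- crossprod(matrix(w, nrow = wd[1]), dym)
    dim(dx) <- d
    return(list(dx = dx, dW = dW))
  }
  # direct kernels: at this package's channel widths they beat building the
  # (C*KH*KW) x (OH*OW*N) column matrix twice
  dW <- .conv_bwd_w_cpp(dy, x, d[1], d[2], d[3], d[4], wd[1], wd[3], wd[4],
                        stride, pad)
  dim(dW) <- wd
  dx <- .conv_bwd_x_cpp(dy, w, d[1], d[2], d[3], d[4], wd[1], wd[3], wd[4],
                        stride, pad)
  dim(dx) <- d
  list(dx = dx, dW = dW)
}

dwconv_fwd <- function(x, w, stride, pad) {
  d <- dim(x); k <- dim(w)[2]
  y <- .dwconv_fwd_cpp(x, w, d[1], d[2], d[3], d[4], k, stride, pad)
  dim(y) <- c(d[1], conv_out_side(d[2], k, stride, pad),
              conv_out_side(d[3], k, stride, pad), d[4])
  y
}

dwconv_bwd <- function(x, w, stride, pad, dy, need_dw = TRUE) {
  d <- dim(x); k <- dim(w)[2]
  dx <- .dwconv_bwd_x_cpp(dy, w, d[1], d[2], d[3], d[4], k, stride, pad)
  dim(dx) <- d
  dW <- NULL
  if (need_dw) {
    dW <- .dwconv_bwd_w_cpp(dy, x, d[1], d[2], d[3], d[4], k, stride, pad)
    dim(dW) <- dim(w)
  }
  list(dx = dx, dW = dW)
}

# 2d batch normalization over (H, W, N) per channel (single-pass C kernels).
bn_fwd <- function(x, gamma, beta, rmean, rvar, training,
                   momentum = 0.1, eps = 1e-5) {
  C <- dim(x)[1]
  if (training) {
    st <- .chan_stats_cpp(x, C)
    ivar <- 1 / sqrt(st$var + eps)
    ap <- .bn_apply_cpp(x, st$mean, ivar, gamma, beta)
    m <- length(x) / C
    unbias <- if (m > 1) m / (m - 1) else 1
    y <- ap$y; dim(y) <- dim(x)
    list(y = y, cache = list(xhat = ap$xhat, ivar = ivar, train = TRUE),
         rmean = (1 - momentum) * rmean + momentum * st$mean,
         rvar = (1 - momentum) * rvar + momentum * st$var * unbias)
  } else {
    ivar <- 1 / sqrt(rvar + eps)
    ap <- .bn_apply_cpp(x, rmean, ivar, gamma, beta)
    y <- ap$y; dim(y) <- dim(x)
    list(y = y, cache = list(xhat = ap$xhat, ivar = ivar, train = FALSE),
         rmean = rmean, rvar = rvar)
  }
}

bn_bwd <- function(cache, gamma, dy) {
  r <- .bn_bwd_cpp(dy, cache$xhat, cache$ivar, gamma, cache$train)
  dx <- r$dx; dim(dx) <- dim(dy)
  list(dx = dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

act_fwd <- function(x, act) {
  switch(act,
    none = x,
    relu = pmax(x, 0),
    silu = x * (1 / (1 + exp(-x))),
    stop("unknown activation: ", act)
  )
}

# `x` is the activation *input* (cached pre-activation).
act_bwd <- function(x, act, dy) {
  switch(act,
    none = dy,
    relu = dy * (x > 0),
    silu = {
      s <- 1 / (1 + exp(-x))
      dy * (s * (1 + x * (1 - s)))
    },
    stop("unknown activation: ", act)
  )
}

# Layer normalization over the feature (first) dimension of a d x T matrix.
ln_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- nrow(x)
  mu <- colMeans(x)
  xc <- x - rep(mu, each = d)
  v <- colMeans(xc * xc)
  ivar <- 1 / sqrt(v + eps)
  xhat <- xc * rep(ivar, each = d)
  list(y = gamma * xhat + beta, cache = list(xhat = xhat, ivar = ivar))
}

ln_bwd <- function(cache, gamma, dy) {
  xhat <- cache$xhat
  d <- nrow(dy)
  dxhat <- dy * gamma
  c1 <- colMeans(dxhat)
  c2 <- colMeans(dxhat * xhat)
  dx <- rep(cache$ivar, each = d) *
    (dxhat - rep(c1, each = d) - xhat * rep(c2, each = d))
  list(dx = dx, dgamma = rowSums(dy * xhat), dbeta = rowSums(dy))
}

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

# Multi-head self-attention over sequences stored as (d, L, B).
mhsa_fwd <- function(x, Wqkv, bqkv, Wo, bo, heads) {
  d <- dim(x)[1]; L <- dim(x)[2]; B <- dim(x)[3]
  dh <- d %/% heads
  xm <- matrix(x, nrow = d)
  qkv <- Wqkv %*% xm + bqkv
  q <- array(qkv[1:d, , drop = FALSE], c(dh, heads, L, B))
  k <- array(qkv[(d + 1):(2 * d), , drop = FALSE], c(dh, heads, L, B))
  v <- array(qkv[(2 * d + 1):(3 * d), , drop = FALSE], c(dh, heads, L, B))
  A <- array(0, c(L, L, heads, B))
  sc <- 1 / sqrt(dh)
  if (L == 1) {
    # one token per sequence: attention is the identity on V
    A[] <- 1
    om <- matrix(v, nrow = d)
  } else {
    o <- array(0, c(dh, heads, L, B))
    for (b in seq_len(B)) {
      for (hd in seq_len(heads)) {
        qb <- array(q[, hd, , b], c(dh, L))
        kb <- array(k[, hd, , b], c(dh, L))
        vb <- array(v[, hd, , b], c(dh, L))
        S <- crossprod(qb, kb) * sc           # S[i, j] = q_i . k_j
        S <- S - S[cbind(seq_len(L), max.col(S, ties.method = "first"))]
        E <- exp(S)
        Ab <- E / rowSums(E)
        A[, , hd, b] <- Ab
        o[, hd, , b] <- vb %*% t(Ab)
      }
    }
    om <- matrix(o, nrow = d)
  }
  y <- Wo %*% om + bo
  list(y = array(y, c(d, L, B)),
       cache = list(xm = xm, qkv = qkv, A = A, om = om))
}

mhsa_bwd <- function(cache, Wqkv, Wo, heads, dy) {
  d <- nrow(Wo); L <- dim(cache$A)[1]; B <- dim(cache$A)[4]
  dh <- d %/% heads
  sc <- 1 / sqrt(dh)
  dym <- matrix(dy, nrow = d)
  dWo <- dym %*% t(cache$om)
  dbo <- rowSums(dym)
  dom <- crossprod(Wo, dym)
  qkv <- cache$qkv
  q <- array(qkv[1:d, , drop = FALSE], c(dh, heads, L, B))
  k <- array(qkv[(d + 1):(2 * d), , drop = FALSE], c(dh, heads, L, B))
  v <- array(qkv[(2 * d + 1):(3 * d), , drop = FALSE], c(dh, heads, L, B))
  do4 <- array(dom, c(dh, heads, L, B))
  dq <- array(0, c(dh, heads, L, B))
  dk <- dq; dv <- dq
  if (L == 1) {
    dv <- do4
  } else for (b in seq_len(B)) {
    for (hd in seq_len(heads)) {
      qb <- array(q[, hd, , b], c(dh, L))
      kb <- array(k[, hd, , b], c(dh, L))
      vb <- array(v[, hd, , b], c(dh, L))
      Ab <- array(cache$A[, , hd, b], c(L, L))
      dob <- array(do4[, hd, , b], c(dh, L))
      dvb <- dob %*% Ab                      # o = v %*% t(A)
      dA <- t(crossprod(vb, dob))            # dA[i, j]
      dS <- (dA - rowSums(dA * Ab)) * Ab     # row-wise softmax backward
      dq[, hd, , b] <- kb %*% t(dS) * sc
      dk[, hd, , b] <- qb %*% dS * sc
      dv[, hd, , b] <- dvb
    }
  }
  dqkv <- rbind(matrix(dq, nrow = d), matrix(dk, nrow = d), matrix(dv, nrow = d))
  dWqkv <- dqkv %*% t(cache$xm)
  dbqkv <- rowSums(dqkv)
  dx <- crossprod(Wqkv, dqkv)
  list(dx = array(dx, c(d, L, dim(dy)[3])),
       dWqkv = dWqkv, dbqkv = dbqkv, dWo = dWo, dbo = dbo)
}

# Patch unfold/fold for MobileViT blocks: sequences run over the patches,
# one sequence per (pixel-position-in-patch, image). Pure permutations, so
# each is the exact adjoint of the other.
unfold_patches <- function(x, p) {
  d <- dim(x)
  nh <- d[2] %/% p; nw <- d[3] %/% p
  dim(x) <- c(d[1], p, nh, p, nw, d[4])
  x <- aperm(x, c(1, 3, 5, 2, 4, 6))
  dim(x) <- c(d[1], nh * nw, p * p * d[4])
  x
}

fold_patches <- function(u, p, H, W, N) {
  d <- dim(u)[1]
  nh <- H %/% p; nw <- W %/% p
  dim(u) <- c(d, nh, nw, p, p, N)
  u <- aperm(u, c(1, 4, 2, 5, 3, 6))
  dim(u) <- c(d, H, W, N)
  u
}

pad_hw <- function(x, ph, pw) {
  if (ph == 0 && pw == 0) return(x)
  d <- dim(x)
  y <- array(0, c(d[1], d[2] + ph, d[3] + pw, d[4]))
  y[, seq_len(d[2]), seq_len(d[3]), ] <- x
  y
}

crop_hw <- function(x, H, W) {
  d <- dim(x)
  if (d[2] == H && d[3] == W) return(x)
  x[, seq_len(H), seq_len(W), , drop = FALSE]
}

global_pool_fwd <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1], d[2] * d[3], d[4])
  y <- matrix(0, d[1], d[4])
  for (n in seq_len(d[4])) {
    y[, n] <- rowMeans(matrix(x[, , n], nrow = d[1]))
  }
  y
}

global_pool_bwd <- function(dfeat, d) {
  hw <- d[2] * d[3]
  dx <- array(0, d)
  per <- dfeat / hw
  for (n in seq_len(d[4])) dx[, , , n] <- per[, n]
  dx
}
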