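# Module tree, parameter registry, forward/backward dispatch and SGD.
#
# A built network is an environment (class "tk_model") holding:
#   arch    - a tree of module nodes (plain lists with $kind/$cfg/$ids/$children)
#   params  - environment: parameter id -> numeric array
#   buffers - environment: BN running statistics
#   meta    - tibble: id, group ("backbone"/"head"), trainable
#   grads   - environment, repopulated every backward pass
#   vel     - environment, SGD momentum state

new_ctx <- function() {
  e <- new.env(parent = emptyenv())
  e$params <- list()
  e$buffers <- list()
  e$meta <- list()
  e
}

ctx_param <- function(ctx, id, value, group = "backbone", trainable = TRUE) {
  if (!is.null(ctx$params[[id]])) stop("duplicate parameter id: ", id)
  ctx$params[[id]] <- value
  ctx$meta[[id]] <- list(id = id, group = group, trainable = trainable,
                         n = length(value))
  id
}

ctx_buffer <- function(ctx, id, value) {
  ctx$buffers[[id]] <- value
  id
}

init_conv_w <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

init_linear_w <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, 0, sqrt(2 / (nin + nout))), nout, nin)
}

# Convolution (+ optional batch norm + activation). `dw = TRUE` makes it
# depthwise (cin must equal cout). Convs followed by a norm carry no bias.
mk_convbn <- function(ctx, path, cin, cout, k, stride = 1, pad = 0,
                      act = "silu", bn = TRUE, bias = FALSE, dw = FALSE,
                      group = "backbone") {
  ids <- list()
  if (dw) {
    stopifnot(cin == cout)
    ids$W <- ctx_param(ctx, paste0(path, ".W"),
                       init_conv_w(c(cout, k, k), k * k), group)
  } else {
    ids$W <- ctx_param(ctx, paste0(path, ".W"),
                       init_conv_w(c(cout, cin, k, k), cin * k * k), group)
  }
  if (bias) ids$b <- ctx_param(ctx, paste0(path, ".b"), numeric(cout), group)
  if (bn) {
    ids$gamma <- ctx_param(ctx, paste0(path, ".gamma"), rep(1, cout), group)
    ids$beta <- ctx_param(ctx, paste0(path, ".beta"), numeric(cout), group)
    ids$rmean <- ctx_buffer(ctx, paste0(path, ".rmean"), numeric(cout))
    ids$rvar <- ctx_buffer(ctx, paste0(path, ".rvar"), rep(1, cout))
  }
  list(kind = "convbn", ids = ids,
       cfg = list(stride = stride, pad = pad, act = act, bn = bn,
                  bias = bias, dw = dw, cin = cin, cout = cout, k = k))
}

mk_avgpool <- function(k = 3, stride = 2, pad = 1) {
  list(kind = "avgpool", ids = list(),
       cfg = list(k = k, stride = stride, pad = pad))
}

mk_mv2 <- function(ctx, path, cin, cout, stride, expansion) {
  hidden <- round(cin * expansion)
  list(kind = "mv2", ids = list(),
       cfg = list(residual = (stride == 1 && cin == cout)),
       children = list(
         expand = mk_convbn(ctx, paste0(path, ".expand"), cin, hidden, 1),
         dwise = mk_convbn(ctx, paste0(path, ".dwise"), hidden, hidden, 3,
                           stride = stride, pad = 1, dw = TRUE),
         proj = mk_convbn(ctx, paste0(path, ".proj"), hidden, cout, 1,
                          act = "none")
       ))
}

mk_tlayer <- function(ctx, path, d, ffn, heads) {
  ids <- list(
    ln1_g = ctx_param(ctx, paste0(path, ".ln1.gamma"), rep(1, d)),
    ln1_b = ctx_param(ctx, paste0(path, ".ln1.beta"), numeric(d)),
    qkv_W = ctx_param(ctx, paste0(path, ".qkv.W"), init_linear_w(3 * d, d)),
    qkv_b = ctx_param(ctx, paste0(path, ".qkv.b"), numeric(3 * d)),
    out_W = ctx_param(ctx, paste0(path, ".out.W"), init_linear_w(d, d)),
    out_b = ctx_param(ctx, paste0(path, ".out.b"), numeric(d)),
    ln2_g = ctx_param(ctx, paste0(path, ".ln2.gamma"), rep(1, d)),
    ln2_b = ctx_param(ctx, paste0(path, ".ln2.beta"), numeric(d)),
    ffn1_W = ctx_param(ctx, paste0(path, ".ffn1.W"), init_linear_w(ffn, d)),
    ffn1_b = ctx_param(ctx, paste0(path, ".ffn1.b"), numeric(ffn)),
    ffn2_W = ctx_param(ctx, paste0(path, ".ffn2.W"), init_linear_w(d, ffn)),
    ffn2_b = ctx_param(ctx, paste0(path, ".ffn2.b"), numeric(d))
  )
  list(ids = ids, cfg = list(d = d, ffn = ffn, heads = heads))
}

# MobileViT block: local 3x3 conv rep, 1x1 to transformer width, unfold,
# pre-LN transformer stack over patches, fold back, 1x1 projection, then a
# 3x3 fusion conv over the concatenation with the block input.
mk_mvit <- function(ctx, path, C, d, depth, ffn, heads, patch) {
  tl <- lapply(seq_len(depth), function(i) {
    mk_tlayer(ctx, paste0(path, ".t", i), d, ffn, heads)
  })
  ids <- list(
    post_g = ctx_param(ctx, paste0(path, ".postln.gamma"), rep(1, d)),
    post_b = ctx_param(ctx, paste0(path, ".postln.beta"), numeric(d))
  )
  list(kind = "mvit", ids = ids,
       cfg = list(C = C, d = d, depth = depth, heads = heads, patch = patch),
       children = list(
         local = mk_convbn(ctx, paste0(path, ".local"), C, C, 3, pad = 1),
         tod = mk_convbn(ctx, paste0(path, ".tod"), C, d, 1,
                         act = "none", bn = FALSE),
         proj = mk_convbn(ctx, paste0(path, ".proj"), d, C, 1),
         fusion = mk_convbn(ctx, paste0(path, ".fusion"), 2 * C, C, 3, pad = 1)
       ),
       tl = tl)
}

# Four-branch multi-scale stem: pooled 1x1, 1x1->3x3, 5x5, 7x7, all at an
# output stride of 2, channel-concatenated in branch order. ReLU + BN per
# branch; convs are bias-free.
mk_msc <- function(ctx, path, cin, branch_out, stride = 2) {
  stopifnot(length(branch_out) == 4, all(branch_out >= 1))
  list(kind = "msc", ids = list(),
       cfg = list(branch_out = branch_out, stride = stride),
       children = list(
         pool = mk_avgpool(3, stride, 1),
         b1 = mk_convbn(ctx, paste0(path, ".b1"), cin, branch_out[1], 1,
                        act = "relu"),
         b2a = mk_convbn(ctx, paste0(path, ".b2a"), cin, branch_out[2], 1,
                         act = "relu"),
         b2b = mk_convbn(ctx, paste0(path, ".b2b"), branch_out[2],
                         branch_out[2], 3, stride = stride, pad = 1,
                         act = "relu"),
         b3 = mk_convbn(ctx, paste0(path, ".b3"), cin, branch_out[3], 5,
                        stride = stride, pad = 2, act = "relu"),
         b4 = mk_convbn(ctx, paste0(path, ".b4"), cin, branch_out[4], 7,
                        stride = stride, pad = 3, act = "relu")
       ))
}

mk_head <- function(ctx, path, cin, nout) {
  list(kind = "head",
       ids = list(
         W = ctx_param(ctx, paste0(path, ".W"), init_linear_w(nout, cin),
                       group = "head"),
         b = ctx_param(ctx, paste0(path, ".b"), numeric(nout), group = "head")
       ),
       cfg = list(cin = cin, nout = nout))
}

P <- function(model, id) model$params[[id]]

acc_grad <- function(model, id, g) {
  old <- model$grads[[id]]
  model$grads[[id]] <- if (is.null(old)) g else old + g
  invisible(NULL)
}

## ---- forward ---------------------------------------------------------------

mod_fwd <- function(node, x, model, training) {
  switch(node$kind,
    convbn = convbn_fwd(node, x, model, training),
    avgpool = {
      C <- dim(x)[1]
      w <- array(1 / (node$cfg$k^2), c(C, node$cfg$k, node$cfg$k))
      list(y = dwconv_fwd(x, w, node$cfg$stride, node$cfg$pad),
           cache = list(dimx = dim(x)))
    },
    mv2 = mv2_fwd(node, x, model, training),
    mvit = mvit_fwd(node, x, model, training),
    msc = msc_fwd(node, x, model, training),
    head = head_fwd(node, x, model),
    stop("unknown module kind: ", node$kind)
  )
}

convbn_fwd <- function(node, x, model, training) {
  cfg <- node$cfg
  w <- P(model, node$ids$W)
  z <- if (cfg$dw) dwconv_fwd(x, w, cfg$stride, cfg$pad)
       else conv_fwd(x, w, cfg$stride, cfg$pad)
  if (cfg$bias) z <- z + P(model, node$ids$b)
  bnc <- NULL
  if (cfg$bn) {
    r <- bn_fwd(z, P(model, node$ids$gamma), P(model, node$ids$beta),
                model$buffers[[node$ids$rmean]], model$buffers[[node$ids$rvar]],
                training)
    if (training) {
      model$buffers[[node$ids$rmean]] <- r$rmean
      model$buffers[[node$ids$rvar]] <- r$rvar
    }
    a <- r$y
    bnc <- r$cache
  } else {
    a <- z
  }
  if (cfg$act == "silu") {
    s <- 1 / (1 + exp(-a))
    y <- a * s
  } else {
    s <- NULL
    y <- act_fwd(a, cfg$act)
  }
  list(y = y, cache = list(x = x, a = a, bn = bnc, s = s))
}

mv2_fwd <- function(node, x, model, training) {
  ch <- node$children
  r1 <- mod_fwd(ch$expand, x, model, training)
  r2 <- mod_fwd(ch$dwise, r1$y, model, training)
  r3 <- mod_fwd(ch$proj, r2$y, model, training)
  y <- if (node$cfg$residual) r3$y + x else r3$y
  list(y = y, cache = list(expand = r1$cache, dwise = r2$cache,
                           proj = r3$cache))
}

tlayer_fwd <- function(tl, u, model) {
  d3 <- dim(u)
  um <- matrix(u, nrow = d3[1])
  l1 <- ln_fwd(um, P(model, tl$ids$ln1_g), P(model, tl$ids$ln1_b))
  at <- mhsa_fwd(array(l1$y, d3), P(model, tl$ids$qkv_W),
                 P(model, tl$ids$qkv_b), P(model, tl$ids$out_W),
                 P(model, tl$ids$out_b), tl$cfg$heads)
  u1 <- um + matrix(at$y, nrow = d3[1])
  l2 <- ln_fwd(u1, P(model, tl$ids$ln2_g), P(model, tl$ids$ln2_b))
  z1 <- P(model, tl$ids$ffn1_W) %*% l2$y + P(model, tl$ids$ffn1_b)
  s <- act_fwd(z1, "silu")
  f <- P(model, tl$ids$ffn2_W) %*% s + P(model, tl$ids$ffn2_b)
  list(y = array(u1 + f, d3),
       cache = list(ln1 = l1$cache, at = at$cache, ln2 = l2$cache,
                    z1 = z1, s = s, h2 = l2$y, d3 = d3))
}

tlayer_bwd <- function(tl, cache, dy, model) {
  d3 <- cache$d3
  du2 <- matrix(dy, nrow = d3[1])
  # FFN branch
  df <- du2
  dW2 <- df %*% t(cache$s)
  db2 <- rowSums(df)
  ds <- crossprod(P(model, tl$ids$ffn2_W), df)
  dz1 <- act_bwd(cache$z1, "silu", ds)
  dW1 <- dz1 %*% t(cache$h2)
  db1 <- rowSums(dz1)
  dh2 <- crossprod(P(model, tl$ids$ffn1_W), dz1)
  l2 <- ln_bwd(cache$ln2, P(model, tl$ids$ln2_g), dh2)
  du1 <- du2 + l2$dx
  # attention branch
  at <- mhsa_bwd(cache$at, P(model, tl$ids$qkv_W), P(model, tl$ids$out_W),
                 tl$cfg$heads, array(du1, d3))
  l1 <- ln_bwd(cache$ln1, P(model, tl$ids$ln1_g), matrix(at$dx, nrow = d3[1]))
  dum <- du1 + l1$dx
  acc_grad(model, tl$ids$ffn2_W, dW2); acc_grad(model, tl$ids$ffn2_b, db2)
  acc_grad(model, tl$ids$ffn1_W, dW1); acc_grad(model, tl$ids$ffn1_b, db1)
  acc_grad(model, tl$ids$ln2_g, l2$dgamma); acc_grad(model, tl$ids$ln2_b, l2$dbeta)
  acc_grad(model, tl$ids$qkv_W, at$dWqkv); acc_grad(model, tl$ids$qkv_b, at$dbqkv)
  acc_grad(model, tl$ids$out_W, at$dWo); acc_grad(model, tl$ids$out_b, at$dbo)
  acc_grad(model, tl$ids$ln1_g, l1$dgamma); acc_grad(model, tl$ids$ln1_b, l1$dbeta)
  array(dum, d3)
}

mvit_fwd <- function(node, x, model, training) {
  cfg <- node$cfg
  H <- dim(x)[2]; W <- dim(x)[3]; N <- dim(x)[4]
  p <- cfg$patch
  rl <- mod_fwd(node$children$local, x, model, training)
  rt <- mod_fwd(node$children$tod, rl$y, model, training)
  Hp <- ceiling(H / p) * p
  Wp <- ceiling(W / p) * p
  zp <- pad_hw(rt$y, Hp - H, Wp - W)
  u <- unfold_patches(zp, p)
  tcaches <- vector("list", length(node$tl))
  for (i in seq_along(node$tl)) {
    r <- tlayer_fwd(node$tl[[i]], u, model)
    u <- r$y
    tcaches[[i]] <- r$cache
  }
  d3 <- dim(u)
  pl <- ln_fwd(matrix(u, nrow = d3[1]), P(model, node$ids$post_g),
               P(model, node$ids$post_b))
  uf <- fold_patches(array(pl$y, d3), p, Hp, Wp, N)
  uf <- crop_hw(uf, H, W)
  rp <- mod_fwd(node$children$proj, uf, model, training)
  cat2 <- rbind(matrix(x, nrow = cfg$C), matrix(rp$y, nrow = cfg$C))
  dim(cat2) <- c(2 * cfg$C, H, W, N)
  rf <- mod_fwd(node$children$fusion, cat2, model, training)
  list(y = rf$y,
       cache = list(local = rl$cache, tod = rt$cache, tl = tcaches,
                    postln = pl$cache, proj = rp$cache, fusion = rf$cache,
                    HW = c(H, W, N), Hp = Hp, Wp = Wp, d3 = d3))
}

msc_fwd <- function(node, x, model, training) {
  ch <- node$children
  rpool <- mod_fwd(ch$pool, x, model, training)
  r1 <- mod_fwd(ch$b1, rpool$y, model, training)
  r2a <- mod_fwd(ch$b2a, x, model, training)
  r2b <- mod_fwd(ch$b2b, r2a$y, model, training)
  r3 <- mod_fwd(ch$b3, x, model, training)
  r4 <- mod_fwd(ch$b4, x, model, training)
  bo <- node$cfg$branch_out
  yd <- dim(r1$y)
  y <- rbind(matrix(r1$y, nrow = bo[1]), matrix(r2b$y, nrow = bo[2]),
             matrix(r3$y, nrow = bo[3]), matrix(r4$y, nrow = bo[4]))
  dim(y) <- c(sum(bo), yd[2], yd[3], yd[4])
  list(y = y, cache = list(pool = rpool$cache, b1 = r1$cache, b2a = r2a$cache,
                           b2b = r2b$cache, b3 = r3$cache, b4 = r4$cache,
                           ydim = yd))
}

head_fwd <- function(node, x, model) {
  feat <- global_pool_fwd(x)
  logits <- P(model, node$ids$W) %*% feat + P(model, node$ids$b)
  list(y = logits, cache = list(dimx = dim(x), feat = feat))
}

## ---- backward --------------------------------------------------------------

mod_bwd <- function(node, cache, dy, model) {
  switch(node$kind,
    convbn = convbn_bwd(node, cache, dy, model),
    avgpool = {
      C <- cache$dimx[1]
      w <- array(1 / (node$cfg$k^2), c(C, node$cfg$k, node$cfg$k))
      x0 <- array(0, cache$dimx)   # input values are irrelevant for dx
      dwconv_bwd(x0, w, node$cfg$stride, node$cfg$pad, dy, need_dw = FALSE)$dx
    },
    mv2 = mv2_bwd(node, cache, dy, model),
    mvit = mvit_bwd(node, cache, dy, model),
    msc = msc_bwd(node, cache, dy, model),
    head = head_bwd(node, cache, dy, model),
    stop("unknown module kind: ", node$kind)
  )
}

convbn_bwd <- function(node, cache, dy, model) {
  cfg <- node$cfg
  da <- if (cfg$act == "silu") {
    s <- cache$s
    dy * (s * (1 + cache$a * (1 - s)))
  } else {
    act_bwd(cache$a, cfg$act, dy)
  }
  if (cfg$bn) {
    r <- bn_bwd(cache$bn, P(model, node$ids$gamma), da)
    acc_grad(model, node$ids$gamma, r$dgamma)
    acc_grad(model, node$ids$beta, r$dbeta)
    dz <- r$dx
  } else {
    dz <- da
  }
  if (cfg$bias) {
    acc_grad(model, node$ids$b, rowSums(matrix(dz, nrow = cfg$cout)))
  }
  w <- P(model, node$ids$W)
  if (cfg$dw) {
    r <- dwconv_bwd(cache$x, w, cfg$stride, cfg$pad, dz)
  } else {
    r <- conv_bwd(cache$x, w, cfg$stride, cfg$pad, dz)
  }
  acc_grad(model, node$ids$W, r$dW)
  r$dx
}

mv2_bwd <- function(node, cache, dy, model) {
  ch <- node$children
  d3 <- mod_bwd(ch$proj, cache$proj, dy, model)
  d2 <- mod_bwd(ch$dwise, cache$dwise, d3, model)
  d1 <- mod_bwd(ch$expand, cache$expand, d2, model)
  if (node$cfg$residual) d1 + dy else d1
}

mvit_bwd <- function(node, cache, dy, model) {
  cfg <- node$cfg
  H <- cache$HW[1]; W <- cache$HW[2]; N <- cache$HW[3]
  p <- cfg$patch
  dcat <- mod_bwd(node$children$fusion, cache$fusion, dy, model)
  dcm <- matrix(dcat, nrow = 2 * cfg$C)
  dskip <- array(dcm[seq_len(cfg$C), , drop = FALSE], c(cfg$C, H, W, N))
  dpr <- array(dcm[cfg$C + seq_len(cfg$C), , drop = FALSE], c(cfg$C, H, W, N))
  duf <- mod_bwd(node$children$proj, cache$proj, dpr, model)
  duf <- pad_hw(duf, cache$Hp - H, cache$Wp - W)   # adjoint of crop
  du <- unfold_patches(duf, p)                      # adjoint of fold
  pl <- ln_bwd(cache$postln, P(model, node$ids$post_g),
               matrix(du, nrow = cfg$d))
  acc_grad(model, node$ids$post_g, pl$dgamma)
  acc_grad(model, node$ids$post_b, pl$dbeta)
  du <- array(pl$dx, cache$d3)
  for (i in rev(seq_along(node$tl))) {
    du <- tlayer_bwd(node$tl[[i]], cache$tl[[i]], du, model)
  }
  dzp <- fold_patches(du, p, cache$Hp, cache$Wp, N)  # adjoint of unfold
  dz <- crop_hw(dzp, H, W)                           # adjoint of pad
  dl <- mod_bwd(node$children$tod, cache$tod, dz, model)
  dx <- mod_bwd(node$children$local, cache$local, dl, model)
  dx + dskip
}

msc_bwd <- function(node, cache, dy, model) {
  ch <- node$children
  bo <- node$cfg$branch_out
  yd <- cache$ydim
  dym <- matrix(dy, nrow = sum(bo))
  off <- cumsum(c(0, bo))
  part <- function(i, nb) {
    array(dym[(off[i] + 1):(off[i] + nb), , drop = FALSE],
          c(nb, yd[2], yd[3], yd[4]))
  }
  dpool_in <- mod_bwd(ch$b1, cache$b1, part(1, bo[1]), model)
  dx1 <- mod_bwd(ch$pool, cache$pool, dpool_in, model)
  d2b <- mod_bwd(ch$b2b, cache$b2b, part(2, bo[2]), model)
  dx2 <- mod_bwd(ch$b2a, cache$b2a, d2b, model)
  dx3 <- mod_bwd(ch$b3, cache$b3, part(3, bo[3]), model)
  dx4 <- mod_bwd(ch$b4, cache$b4, part(4, bo[4]), model)
  dx1 + dx2 + dx3 + dx4
}

head_bwd <- function(node, cache, dlogits, model) {
  acc_grad(model, node$ids$W, dlogits %*% t(cache$feat))
  acc_grad(model, node$ids$b, rowSums(dlogits))
  dfeat <- crossprod(P(model, node$ids$W), dlogits)
  global_pool_bwd(dfeat, cache$dimx)
}

## ---- whole network ---------------------------------------------------------

net_forward <- function(model, x, training = FALSE, want_cache = FALSE,
                        record_stages = FALSE) {
  stages <- model$arch
  caches <- if (want_cache) vector("list", length(stages)) else NULL
  outs <- if (record_stages) vector("list", length(stages)) else NULL
  for (i in seq_along(stages)) {
    r <- mod_fwd(stages[[i]], x, model, training)
    x <- r$y
    if (want_cache) caches[[i]] <- r$cache
    if (record_stages) outs[[i]] <- x
  }
  if (record_stages) names(outs) <- names(stages)
  list(logits = x, caches = caches, stages = outs)
}

# Backpropagate dlogits; gradients accumulate in model$grads. If
# `stop_stage` names a stage, returns the gradient with respect to that
# stage's *output* (used by Grad-CAM) without descending further.
net_backward <- function(model, caches, dlogits, stop_stage = NULL) {
  stages <- model$arch
  nm <- names(stages)
  dy <- dlogits
  for (i in rev(seq_along(stages))) {
    if (!is.null(stop_stage) && nm[i] == stop_stage) return(dy)
    dy <- mod_bwd(stages[[i]], caches[[i]], dy, model)
  }
  dy
}

zero_grads <- function(model) {
  model$grads <- new.env(parent = emptyenv())
  invisible(model)
}

sgd_step <- function(model, lr_backbone, lr_head, momentum = 0.9,
                     weight_decay = 5e-4) {
  for (m in model$meta_list) {
    if (!m$trainable) next
    g <- model$grads[[m$id]]
    if (is.null(g)) next
    p <- model$params[[m$id]]
    g <- g + weight_decay * p
    v <- model$vel[[m$id]]
    v <- if (is.null(v)) g else momentum * v + g
    model$vel[[m$id]] <- v
    lr <- if (m$group == "head") lr_head else lr_backbone
    model$params[[m$id]] <- p - lr * v
  }
  invisible(model)
}

finalize_model <- function(ctx, arch, role, class_nodes, variant, stem,
                           input_side) {
  m <- new.env(parent = emptyenv())
  m$arch <- arch
  m$params <- list2env(ctx$params, parent = emptyenv())
  m$buffers <- list2env(ctx$buffers, parent = emptyenv())
  m$meta_list <- unname(ctx$meta)
  m$meta <- dplyr::bind_rows(lapply(ctx$meta, tibble::as_tibble))
  m$grads <- new.env(parent = emptyenv())
  m$vel <- new.env(parent = emptyenv())
  m$role <- role
  m$class_nodes <- class_nodes
  m$variant <- variant
  m$stem <- stem
  m$input_side <- input_side
  m$num_nodes <- length(class_nodes)
  m$log <- NULL
  class(m) <- "tk_model"
  m
}
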