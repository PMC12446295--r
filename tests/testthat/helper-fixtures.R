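# Shared fixtures, all generated in code at test time.

# Small in-memory dataset with the package's synthetic class motifs.
# `style_rows` selects rows of class_styles(10) (e.g. maximally distinct
# motifs for quick separability checks).
make_synth_dataset <- function(counts, side = 32L, seed = 1L, noise_sd = 4,
                               style_rows = NULL) {
  cfg <- synthetic_config(counts = counts, side = side, noise_sd = noise_sd,
                          seed = seed)
  if (!is.null(style_rows)) cfg$styles <- class_styles(10)[style_rows, ]
  imgs <- list()
  y <- integer()
  for (i in seq_along(counts)) {
    st <- tailkd:::render_class_stack(cfg, i, counts[i])
    imgs <- c(imgs, st)
    y <- c(y, rep(i, length(st)))
  }
  pack_images(imgs, y, names(counts), side)
}

# Naive direct convolution, the independent oracle for the GEMM path.
naive_conv <- function(x, w, stride, pad) {
  d <- dim(x); wd <- dim(w)
  OH <- (d[2] + 2 * pad - wd[3]) %/% stride + 1
  OW <- (d[3] + 2 * pad - wd[4]) %/% stride + 1
  y <- array(0, c(wd[1], OH, OW, d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(wd[1])) {
    for (oh in seq_len(OH)) for (ow in seq_len(OW)) {
      acc <- 0
      for (ci in seq_len(d[1])) for (ki in seq_len(wd[3])) {
        for (kj in seq_len(wd[4])) {
          h <- (oh - 1) * stride - pad + ki
          w_ <- (ow - 1) * stride - pad + kj
          if (h >= 1 && h <= d[2] && w_ >= 1 && w_ <= d[3]) {
            acc <- acc + x[ci, h, w_, n] * w[co, ci, ki, kj]
          }
        }
      }
      y[co, oh, ow, n] <- acc
    }
  }
  y
}

# Relative error between analytic gradient and a central finite difference
# of `fn` (scalar-valued) at coordinate i of parameter vector v.
fd_rel_error <- function(fn, v, grad, i, eps = 1e-5) {
  vp <- v; vp[i] <- vp[i] + eps
  vm <- v; vm[i] <- vm[i] - eps
  fd <- (fn(vp) - fn(vm)) / (2 * eps)
  abs(grad[i] - fd) / max(abs(fd), abs(grad[i]), 1e-10)
}

shannon_entropy <- function(p) -sum(p * log(p))

# Reconstructing a confusion matrix whose per-class recalls and test
# sizes are given: diagonal = correct counts, remainder of each row
# dumped on some other class.
cm_from_recalls <- function(recall, n, class_names) {
  K <- length(n)
  correct <- round_half_up(recall * n / 100)
  cm <- matrix(0L, K, K, dimnames = list(true = class_names,
                                         predicted = class_names))
  for (i in seq_len(K)) {
    cm[i, i] <- correct[i]
    if (n[i] > correct[i]) cm[i, i %% K + 1] <- n[i] - correct[i]
  }
  class(cm) <- c("tk_confusion", class(cm))
  cm
}

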