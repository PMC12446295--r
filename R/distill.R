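# Logit splicing, tempered soft labels, the distillation loss stack and
# student training against the frozen expert ensemble.

#' Distillation configuration
#'
#' @param temperature Softmax temperature `T > 0` used for both teacher
#'   and student soft labels.
#' @param alpha Weight of the soft loss in the combined loss
#'   `alpha * L_soft + (1 - alpha) * L_hard`.
#' @param orientation `"standard"` treats the teacher distribution as the
#'   cross-entropy target (`-sum q log p`, the usual KD direction);
#'   `"as-printed"` computes `-sum p log q` with the student distribution
#'   as the outer weight.
#' @param hard_loss `"cross-entropy"` or `"focal"` (focal factor
#'   `(1 - p_true)^gamma`).
#' @param gamma Focal exponent.
#' @param t2_scale Multiply the soft loss by `T^2` (classic KD gradient
#'   rebalancing; off by default).
#' @return A `tk_distill_config` list.
#' @export
distill_config <- function(temperature = 4, alpha = 0.5,
                           orientation = c("standard", "as-printed"),
                           hard_loss = c("cross-entropy", "focal"),
                           gamma = 2, t2_scale = FALSE) {
  if (temperature <= 0) rlang::abort("`temperature` must be > 0")
  if (alpha < 0 || alpha > 1) rlang::abort("`alpha` must be in [0, 1]")
  structure(list(temperature = temperature, alpha = alpha,
                 orientation = match.arg(orientation),
                 hard_loss = match.arg(hard_loss), gamma = gamma,
                 t2_scale = t2_scale),
            class = "tk_distill_config")
}

#' Temperature-scaled softmax
#'
#' `q_i = exp(z_i / T) / sum_j exp(z_j / T)`, numerically stabilized by
#' max subtraction. Larger `T` yields a higher-entropy distribution.
#'
#' @param z Logit vector, or matrix with one column per sample.
#' @param temperature `T > 0`.
#' @return Probabilities of the same shape, columns summing to 1.
#' @export
tempered_softmax <- function(z, temperature = 4) {
  if (temperature <= 0) rlang::abort("`temperature` must be > 0")
  if (is.matrix(z)) softmax_cols(z / temperature)
  else as.vector(softmax_cols(matrix(z / temperature)))
}

#' Splice expert logits into a global logit vector
#'
#' Drops each expert's trailing "other" node and concatenates the
#' remaining nodes in global class order (head block, then balance, then
#' tail). With groups of sizes (2, 3, 4) this yields the full 9-way logit
#' vector.
#'
#' @param expert_outputs Named list (one element per group present in
#'   `assignment`) of logit vectors or `nodes x N` matrices, each with
#'   `group size + 1` rows.
#' @param assignment A `tk_groups` assignment (defines group order and the
#'   per-group class lists).
#' @return Logit vector/matrix over all classes, in global order, with
#'   class names.
#' @export
splice_expert_logits <- function(expert_outputs, assignment) {
  gl <- group_classes(assignment)
  gl <- gl[lengths(gl) > 0]
  missing <- setdiff(names(gl), names(expert_outputs))
  if (length(missing)) {
    rlang::abort(sprintf("missing expert output for group(s): %s",
                         paste(missing, collapse = ", ")))
  }
  blocks <- lapply(names(gl), function(g) {
    z <- expert_outputs[[g]]
    if (is.vector(z)) z <- matrix(z)
    k <- length(gl[[g]])
    if (nrow(z) != k + 1) {
      rlang::abort(sprintf(
        "expert for group %s has %d nodes, expected %d (+1 for 'other')",
        g, nrow(z), k + 1))
    }
    z[seq_len(k), , drop = FALSE]
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- unlist(gl, use.names = FALSE)
  if (ncol(out) == 1 && is.null(dim(expert_outputs[[1]]))) out <- out[, 1]
  out
}

#' Ensemble prediction from spliced expert logits
#'
#' Softmax (at `T = 1`) over the spliced logits; ties broken by the lowest
#' class index.
#'
#' @inheritParams splice_expert_logits
#' @return Integer global class ids (named with class labels).
#' @export
ensemble_predict <- function(expert_outputs, assignment) {
  z <- splice_expert_logits(expert_outputs, assignment)
  if (is.vector(z)) z <- matrix(z, dimnames = list(names(z)))
  p <- softmax_cols(z)
  idx <- apply(p, 2, which.max)   # first maximum = lowest class index
  stats::setNames(as.integer(idx), rownames(z)[idx])
}

#' Soft (distillation) loss
#'
#' `"standard"` orientation: cross-entropy of the student distribution
#' against the teacher target, `-sum_i q_i log p_i`. `"as-printed"`
#' orientation: `-sum_i p_i log q_i`. Matrices average over columns.
#'
#' @param p Student soft label (from [tempered_softmax()] of student
#'   logits).
#' @param q Teacher soft label.
#' @param cfg A [distill_config()].
#' @return Scalar loss value.
#' @export
soft_loss <- function(p, q, cfg = distill_config()) {
  if (length(p) != length(q)) rlang::abort("p and q have different lengths")
  pm <- if (is.matrix(p)) p else matrix(p)
  qm <- if (is.matrix(q)) q else matrix(q)
  v <- if (cfg$orientation == "standard") {
    -mean(colSums(qm * log(pmax(pm, 1e-12))))
  } else {
    -mean(colSums(pm * log(pmax(qm, 1e-12))))
  }
  if (cfg$t2_scale) v <- v * cfg$temperature^2
  v
}

#' Hard (ground-truth) loss
#'
#' Cross-entropy of `softmax(v)` at the true class; the focal variant
#' multiplies by `(1 - p_true)^gamma` (gamma = 0 recovers plain
#' cross-entropy).
#'
#' @param v Student logit vector, or matrix with one column per sample.
#' @param true_class Integer true class id(s) (1-based).
#' @param cfg A [distill_config()].
#' @return Scalar loss value (mean over samples).
#' @export
hard_loss <- function(v, true_class, cfg = distill_config()) {
  vm <- if (is.matrix(v)) v else matrix(v)
  if (length(true_class) == 1 && ncol(vm) > 1) {
    true_class <- rep(true_class, ncol(vm))
  }
  if (any(true_class < 1 | true_class > nrow(vm))) {
    rlang::abort("true class id out of range")
  }
  p <- softmax_cols(vm)
  pt <- pmax(p[cbind(true_class, seq_len(ncol(vm)))], 1e-12)
  ce <- -log(pt)
  if (cfg$hard_loss == "focal") ce <- (1 - pt)^cfg$gamma * ce
  mean(ce)
}

#' Combined distillation loss
#'
#' Exact affine combination `alpha * L_soft + (1 - alpha) * L_hard`.
#'
#' @param l_soft,l_hard Component loss values.
#' @param alpha Soft-loss weight in `[0, 1]`.
#' @return Scalar.
#' @export
combined_loss <- function(l_soft, l_hard, alpha = 0.5) {
  if (alpha < 0 || alpha > 1) rlang::abort("`alpha` must be in [0, 1]")
  alpha * l_soft + (1 - alpha) * l_hard
}

#' Analytic gradients of the loss stack with respect to student logits
#'
#' Used by the distillation training loop and verifiable against central
#' finite differences. All gradients are per-sample (no batch averaging).
#'
#' @param v Student logit vector or `K x N` matrix.
#' @param q Teacher soft label(s), same shape.
#' @param cfg A [distill_config()].
#' @return Gradient array of `soft_loss` with respect to `v`.
#' @export
soft_loss_grad <- function(v, q, cfg = distill_config()) {
  vm <- if (is.matrix(v)) v else matrix(v)
  qm <- if (is.matrix(q)) q else matrix(q)
  Tt <- cfg$temperature
  p <- softmax_cols(vm / Tt)
  g <- if (cfg$orientation == "standard") {
    (p - qm) / Tt
  } else {
    lq <- log(pmax(qm, 1e-12))
    (p / Tt) * (-lq + rep(colSums(p * lq), each = nrow(p)))
  }
  if (cfg$t2_scale) g <- g * Tt^2
  if (is.matrix(v)) g else as.vector(g)
}

#' @rdname soft_loss_grad
#' @param true_class Integer true class id(s).
#' @export
hard_loss_grad <- function(v, true_class, cfg = distill_config()) {
  vm <- if (is.matrix(v)) v else matrix(v)
  if (length(true_class) == 1 && ncol(vm) > 1) {
    true_class <- rep(true_class, ncol(vm))
  }
  p <- softmax_cols(vm)
  n <- ncol(vm)
  ii <- cbind(true_class, seq_len(n))
  if (cfg$hard_loss == "cross-entropy") {
    g <- p
    g[ii] <- g[ii] - 1
  } else {
    pt <- pmax(p[ii], 1e-12)
    dldpt <- cfg$gamma * (1 - pt)^(cfg$gamma - 1) * log(pt) -
      (1 - pt)^cfg$gamma / pt
    # dpt/dv_i = pt * (delta_it - p_i)
    g <- -p * rep(dldpt * pt, each = nrow(p))
    g[ii] <- g[ii] + dldpt * pt
  }
  if (is.matrix(v)) g else as.vector(g)
}

#' @rdname soft_loss_grad
#' @export
distill_grad <- function(v, q, true_class, cfg = distill_config()) {
  a <- cfg$alpha
  a * soft_loss_grad(v, q, cfg) + (1 - a) * hard_loss_grad(v, true_class, cfg)
}

#' Teacher spliced logits for a dataset
#'
#' Runs every expert (in evaluation mode) over the data and splices the
#' per-group logits into global logit vectors. Because the experts are
#' frozen during distillation this is computed once per dataset.
#'
#' @param experts Named list of trained expert `tk_model`s (names =
#'   groups).
#' @param data A `tk_dataset`.
#' @param assignment A `tk_groups` assignment.
#' @param batch_size Forward batch size.
#' @return `K x N` spliced logit matrix.
#' @export
teacher_logits <- function(experts, data, assignment, batch_size = 64L) {
  outs <- lapply(experts, function(e) model_forward(e, data, batch_size))
  splice_expert_logits(outs, assignment)
}

#' Distill the expert ensemble into a student
#'
#' Trains the student with the combined loss
#' `alpha * L_soft + (1 - alpha) * L_hard`: per batch the teacher soft
#' labels are the tempered softmax of the spliced expert logits (frozen,
#' no gradient), the soft term compares them with the student's tempered
#' softmax, and the hard term is the ground-truth loss on the student
#' logits. The schedule contract is identical to [train_model()].
#'
#' @param student A `tk_model` with one output node per global class.
#' @param experts Named list of trained expert models.
#' @param data Training `tk_dataset` with global labels.
#' @param assignment A `tk_groups` assignment.
#' @param cfg A [train_config()].
#' @param dcfg A [distill_config()].
#' @param quiet Suppress progress messages.
#' @return The trained student, invisibly.
#' @export
distill_student <- function(student, experts, data, assignment,
                            cfg = train_config(), dcfg = distill_config(),
                            quiet = TRUE) {
  if (student$num_nodes != length(data$class_names)) {
    rlang::abort("student output nodes do not match the global class count")
  }
  zt <- teacher_logits(experts, data, assignment)
  if (nrow(zt) != student$num_nodes) {
    rlang::abort("spliced teacher logits do not match student output length")
  }
  q_all <- tempered_softmax(zt, dcfg$temperature)
  train_loop(student, data, cfg, function(logits, bidx) {
    q <- q_all[, bidx, drop = FALSE]
    y <- data$y[bidx]
    p <- tempered_softmax(logits, dcfg$temperature)
    ls <- soft_loss(p, q, dcfg)
    lh <- hard_loss(logits, y, dcfg)
    list(loss = combined_loss(ls, lh, dcfg$alpha),
         dlogits = distill_grad(logits, q, y, dcfg) / length(bidx))
  }, quiet = quiet)
}

#' Export teacher soft labels to CSV
#'
#' Writes one row per sample with the spliced, temperature-softened
#' ensemble distribution over the global classes, for inspection.
#'
#' @inheritParams teacher_logits
#' @param temperature Softmax temperature.
#' @param path Output CSV path.
#' @return The soft-label tibble, invisibly.
#' @export
export_soft_labels <- function(experts, data, assignment, temperature = 4,
                               path) {
  zt <- teacher_logits(experts, data, assignment)
  q <- tempered_softmax(zt, temperature)
  df <- tibble::as_tibble(t(q))
  df <- dplyr::bind_cols(
    tibble::tibble(sample = seq_len(ncol(q)),
                   true_class = data$class_names[data$y]), df)
  readr::write_csv(df, path)
  invisible(df)
}
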