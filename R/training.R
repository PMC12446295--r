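# Group relabeling and the SGD training loop.

#' Training configuration
#'
#' The reference schedule: SGD with momentum 0.9 and weight decay 5e-4,
#' backbone learning rate 0.001, head learning rate 0.01, batch size 32,
#' 200 epochs, cosine annealing decaying each learning rate to 1/1000 of
#' its initial value by the final epoch.
#'
#' @param epochs Number of full training passes (>= 1).
#' @param batch_size Mini-batch size.
#' @param lr_backbone,lr_head Initial learning rates of the two parameter
#'   groups.
#' @param momentum,weight_decay SGD settings.
#' @param lr_final_frac Final learning rate as a fraction of the initial.
#' @param seed Seed governing shuffling (weight init is seeded at build
#'   time).
#' @param pretrained Optional checkpoint path to warm-start matching
#'   parameters from.
#' @return A `tk_train_config` list.
#' @export
train_config <- function(epochs = 200L, batch_size = 32L, lr_backbone = 0.001,
                         lr_head = 0.01, momentum = 0.9, weight_decay = 5e-4,
                         lr_final_frac = 1e-3, seed = 1L, pretrained = NULL) {
  if (epochs < 1) rlang::abort("`epochs` must be >= 1")
  if (lr_backbone <= 0 || lr_head <= 0) {
    rlang::abort("learning rates must be positive")
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_backbone = lr_backbone, lr_head = lr_head,
                 momentum = momentum, weight_decay = weight_decay,
                 lr_final_frac = lr_final_frac, seed = as.integer(seed),
                 pretrained = pretrained),
            class = "tk_train_config")
}

#' Learning rate at a given epoch
#'
#' Cosine interpolation from the initial rate at epoch 0 down to
#' `lr * lr_final_frac` at the final epoch; the midpoint epoch sits at the
#' arithmetic mean of the two.
#'
#' @param cfg A [train_config()].
#' @param epoch Zero-based epoch index, `0 <= epoch < epochs`.
#' @return Named vector with `backbone` and `head` rates.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  if (epoch < 0 || epoch >= cfg$epochs) {
    rlang::abort(sprintf("epoch %d outside [0, %d)", epoch, cfg$epochs))
  }
  frac <- if (cfg$epochs == 1) 1 else {
    f <- cfg$lr_final_frac
    f + (1 - f) * (1 + cos(pi * epoch / (cfg$epochs - 1))) / 2
  }
  c(backbone = cfg$lr_backbone * frac, head = cfg$lr_head * frac)
}

#' Map global labels to a group's local labels
#'
#' In-group classes keep their relative (global) order as local ids
#' `1..k`; every other class maps to the open-set "other" id `k + 1`.
#'
#' @param group Ordered character vector of in-group class names.
#' @param all_classes Global class order.
#' @return Tibble with `class`, `global_id`, `local_id`.
#' @export
group_label_map <- function(group, all_classes) {
  if (!all(group %in% all_classes)) {
    rlang::abort("group contains classes outside the global class set")
  }
  other <- length(group) + 1L
  tibble::tibble(
    class = all_classes,
    global_id = seq_along(all_classes),
    local_id = ifelse(all_classes %in% group,
                      match(all_classes, group), other)
  )
}

#' Relabel global labels for one expert group
#'
#' @param labels Integer global labels (`1..K`).
#' @param group Ordered in-group class names.
#' @param all_classes Global class order.
#' @return Integer local labels (`k + 1` = "other").
#' @export
relabel_for_group <- function(labels, group, all_classes) {
  map <- group_label_map(group, all_classes)
  if (any(labels < 1 | labels > length(all_classes))) {
    rlang::abort("labels outside the global class set")
  }
  as.integer(map$local_id[labels])
}

#' Relabel a dataset for one expert group
#'
#' @param data A `tk_dataset` with global labels.
#' @param group Ordered in-group class names.
#' @return A `tk_dataset` whose classes are `c(group, "other")`.
#' @export
group_dataset <- function(data, group) {
  y <- relabel_for_group(data$y, group, data$class_names)
  tk_dataset(data$x, y, c(group, "other"))
}

# softmax cross-entropy value + gradient wrt logits, averaged over the batch
ce_loss_grad <- function(logits, y) {
  p <- softmax_cols(logits)
  B <- ncol(logits)
  picked <- p[cbind(y, seq_len(B))]
  d <- p
  d[cbind(y, seq_len(B))] <- picked - 1
  list(loss = -mean(log(pmax(picked, 1e-12))), dlogits = d / B)
}

warm_start <- function(model, path) {
  ck <- load_checkpoint(path)
  for (id in ls(ck$params)) {
    cur <- model$params[[id]]
    if (!is.null(cur) && identical(dim(cur), dim(ck$params[[id]])) &&
        length(cur) == length(ck$params[[id]])) {
      model$params[[id]] <- ck$params[[id]]
    }
  }
  invisible(model)
}

train_loop <- function(model, data, cfg, grad_fn, quiet = TRUE) {
  n <- length(data$y)
  if (n == 0) rlang::abort("cannot train on an empty dataset")
  if (!is.null(cfg$pretrained)) warm_start(model, cfg$pretrained)
  logs <- vector("list", cfg$epochs)
  withr::with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs) - 1L) {
      lrs <- lr_at_epoch(cfg, epoch)
      ord <- sample.int(n)
      tot_loss <- 0; correct <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        bidx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        zero_grads(model)
        fw <- net_forward(model, data$x[, , , bidx, drop = FALSE],
                          training = TRUE, want_cache = TRUE)
        gl <- grad_fn(fw$logits, bidx)
        net_backward(model, fw$caches, gl$dlogits)
        sgd_step(model, lrs[["backbone"]], lrs[["head"]], cfg$momentum,
                 cfg$weight_decay)
        tot_loss <- tot_loss + gl$loss * length(bidx)
        pred <- max.col(t(fw$logits), ties.method = "first")
        correct <- correct + sum(pred == data$y[bidx])
      }
      logs[[epoch + 1L]] <- tibble::tibble(
        epoch = epoch, loss = tot_loss / n,
        lr_backbone = lrs[["backbone"]], lr_head = lrs[["head"]],
        train_acc = correct / n)
      if (!quiet) {
        message(sprintf("epoch %3d  loss %.4f  acc %.3f", epoch,
                        tot_loss / n, correct / n))
      }
    }
  })
  model$log <- dplyr::bind_rows(logs)
  invisible(model)
}

#' Train a model with hard labels
#'
#' Plain softmax cross-entropy training under the two-group SGD schedule
#' (backbone and head learning rates, cosine decay). Deterministic given
#' the config seed. The model environment is updated in place and
#' returned; the per-epoch log is available at `model$log` and via
#' `tidy()`.
#'
#' @param model A `tk_model`.
#' @param data A `tk_dataset`; labels must fit the model's output nodes.
#' @param cfg A [train_config()].
#' @param quiet Suppress per-epoch messages.
#' @return The trained model, invisibly.
#' @export
train_model <- function(model, data, cfg = train_config(), quiet = TRUE) {
  if (length(data$y) == 0) rlang::abort("cannot train on an empty dataset")
  if (max(data$y) > model$num_nodes) {
    rlang::abort(sprintf("label id %d exceeds the model's %d output nodes",
                         max(data$y), model$num_nodes))
  }
  train_loop(model, data, cfg, function(logits, bidx) {
    ce_loss_grad(logits, data$y[bidx])
  }, quiet = quiet)
}

#' Build and train one open-set expert
#'
#' Composition of [build_expert()], [group_dataset()] and [train_model()]:
#' relabels the training data so out-of-group samples become "other", then
#' trains the group's expert.
#'
#' @param group Ordered in-group class names (from [group_classes()]).
#' @param data Training `tk_dataset` with global labels.
#' @param cfg A [train_config()].
#' @param variant Expert backbone variant.
#' @param seed Weight-initialization seed.
#' @param quiet Suppress progress messages.
#' @return The trained expert `tk_model`.
#' @export
train_expert <- function(group, data, cfg = train_config(), variant = "s",
                         seed = 1L, quiet = TRUE) {
  if (length(group) == 0) rlang::abort("expert group is empty")
  model <- build_expert(group, variant = variant, seed = seed)
  train_model(model, group_dataset(data, group), cfg, quiet = quiet)
}
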