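#' Backbone configurations
#'
#' Returns the stage configuration of a MobileViT-family backbone. The
#' `"xxs"` and `"s"` variants follow the published MobileViT
#' configurations (inverted-residual expansion 2 and 4 respectively,
#' transformer widths 64/80/96 and 144/192/240, four attention heads).
#' `"test-tiny"` is a strictly smaller variant (halved widths and
#' single-layer transformer stacks, 64x64 input) intended for CPU-scale
#' experiments; it is never used for the parameter audit.
#'
#' @param variant One of `"xxs"`, `"s"`, `"test-tiny"`.
#' @return A list describing stem width, expansion factor, attention heads,
#'   per-stage settings and the final 1x1 conv width.
#' @export
backbone_config <- function(variant = c("xxs", "s", "test-tiny")) {
  variant <- match.arg(variant)
  cfg <- switch(variant,
    "xxs" = list(
      stem_out = 16L, expansion = 2, heads = 4L, input_side = 224L,
      stages = list(
        list(type = "mv2", out = 16L, stride = 1L, repeats = 1L),
        list(type = "mv2", out = 24L, stride = 2L, repeats = 3L),
        list(type = "mvit", out = 48L, stride = 2L, dim = 64L, depth = 2L,
             ffn = 128L, patch = 2L),
        list(type = "mvit", out = 64L, stride = 2L, dim = 80L, depth = 4L,
             ffn = 160L, patch = 2L),
        list(type = "mvit", out = 80L, stride = 2L, dim = 96L, depth = 3L,
             ffn = 192L, patch = 2L)
      ),
      final_out = 320L
    ),
    "s" = list(
      stem_out = 16L, expansion = 4, heads = 4L, input_side = 224L,
      stages = list(
        list(type = "mv2", out = 32L, stride = 1L, repeats = 1L),
        list(type = "mv2", out = 64L, stride = 2L, repeats = 3L),
        list(type = "mvit", out = 96L, stride = 2L, dim = 144L, depth = 2L,
             ffn = 288L, patch = 2L),
        list(type = "mvit", out = 128L, stride = 2L, dim = 192L, depth = 4L,
             ffn = 384L, patch = 2L),
        list(type = "mvit", out = 160L, stride = 2L, dim = 240L, depth = 3L,
             ffn = 480L, patch = 2L)
      ),
      final_out = 640L
    ),
    "test-tiny" = list(
      stem_out = 8L, expansion = 2, heads = 2L, input_side = 64L,
      stages = list(
        list(type = "mv2", out = 8L, stride = 1L, repeats = 1L),
        list(type = "mv2", out = 12L, stride = 2L, repeats = 1L),
        list(type = "mvit", out = 16L, stride = 2L, dim = 24L, depth = 1L,
             ffn = 48L, patch = 2L),
        list(type = "mvit", out = 24L, stride = 2L, dim = 32L, depth = 1L,
             ffn = 64L, patch = 2L),
        list(type = "mvit", out = 32L, stride = 2L, dim = 32L, depth = 1L,
             ffn = 64L, patch = 2L)
      ),
      final_out = 64L
    )
  )
  cfg$variant <- variant
  cfg
}

#' Multi-scale convolution stem specification
#'
#' The four-branch stem that replaces the backbone's first convolution:
#' branch 1 pools 3x3 (stride 2) then lifts channels with a 1x1 conv;
#' branch 2 is 1x1 followed by a strided 3x3; branches 3 and 4 are strided
#' 5x5 and 7x7 convs. Each branch ends in BN + ReLU and the outputs are
#' concatenated along channels, so `sum(branch_out)` must equal the stem
#' width of the host backbone.
#'
#' @param in_channels Input channels (3 for RGB).
#' @param branch_out Integer vector of 4 per-branch output channel counts.
#' @param stride Spatial stride of the stem (2).
#' @return A `tk_msc_spec` list.
#' @export
msc_spec <- function(in_channels = 3L, branch_out = c(4L, 4L, 4L, 4L),
                     stride = 2L) {
  if (length(branch_out) != 4 || any(branch_out < 1)) {
    rlang::abort("`branch_out` must be four positive channel counts")
  }
  if (stride < 1) rlang::abort("`stride` must be >= 1")
  structure(list(in_channels = as.integer(in_channels),
                 branch_out = as.integer(branch_out),
                 stride = as.integer(stride)),
            class = "tk_msc_spec")
}

build_backbone_arch <- function(ctx, cfg, stem, msc, num_nodes) {
  stages <- list()
  if (stem == "msc") {
    if (sum(msc$branch_out) != cfg$stem_out) {
      rlang::abort(sprintf(
        "MSC branch channels sum to %d but the %s stem width is %d",
        sum(msc$branch_out), cfg$variant, cfg$stem_out))
    }
    stages$stem <- mk_msc(ctx, "stem", msc$in_channels, msc$branch_out,
                          msc$stride)
  } else {
    stages$stem <- mk_convbn(ctx, "stem", 3L, cfg$stem_out, 3, stride = 2,
                             pad = 1)
  }
  cin <- cfg$stem_out
  for (i in seq_along(cfg$stages)) {
    st <- cfg$stages[[i]]
    nm <- paste0("stage", i)
    if (st$type == "mv2") {
      blocks <- list()
      for (r in seq_len(st$repeats)) {
        blocks[[r]] <- mk_mv2(ctx, paste0(nm, ".b", r), cin, st$out,
                              if (r == 1) st$stride else 1L, cfg$expansion)
        cin <- st$out
      }
      # flatten repeats into individually named stages for Grad-CAM access
      for (r in seq_along(blocks)) {
        stages[[if (length(blocks) == 1) nm else paste0(nm, letters[r])]] <-
          blocks[[r]]
      }
    } else {
      stages[[paste0(nm, ".down")]] <- mk_mv2(ctx, paste0(nm, ".down"), cin,
                                              st$out, st$stride,
                                              cfg$expansion)
      cin <- st$out
      stages[[nm]] <- mk_mvit(ctx, nm, cin, st$dim, st$depth, st$ffn,
                              cfg$heads, st$patch)
    }
  }
  stages$conv_final <- mk_convbn(ctx, "conv_final", cin, cfg$final_out, 1)
  stages$classifier <- mk_head(ctx, "classifier", cfg$final_out, num_nodes)
  stages
}

build_network <- function(num_nodes, variant, stem, msc, role, class_nodes,
                          seed) {
  cfg <- backbone_config(variant)
  withr::with_seed(seed, {
    ctx <- new_ctx()
    arch <- build_backbone_arch(ctx, cfg, stem, msc, num_nodes)
    finalize_model(ctx, arch, role, class_nodes, variant, stem,
                   cfg$input_side)
  })
}

#' Build the MSC-MobileViT student network
#'
#' MobileViT backbone with the first convolution replaced by the
#' four-branch multi-scale stem ([msc_spec()]) and a classifier head sized
#' to `num_classes`. With the default `"xxs"` backbone and 9 classes the
#' trainable parameter count rounds to 0.95 M.
#'
#' @param num_classes Number of output classes (>= 2).
#' @param variant Backbone variant, see [backbone_config()].
#' @param msc Stem specification; defaults to an equal four-way split of
#'   the backbone stem width.
#' @param class_names Optional class labels for the output nodes.
#' @param seed Seed for weight initialization.
#' @return A `tk_model`.
#' @examples
#' student <- build_student(9, variant = "test-tiny")
#' count_parameters(student)
#' @export
build_student <- function(num_classes, variant = "xxs", msc = NULL,
                          class_names = NULL, seed = 1L) {
  if (num_classes < 2) rlang::abort("`num_classes` must be >= 2")
  cfg <- backbone_config(variant)
  if (is.null(msc)) {
    per <- cfg$stem_out %/% 4L
    msc <- msc_spec(3L, rep(per, 4L))
  }
  if (is.null(class_names)) class_names <- paste0("class", seq_len(num_classes))
  stopifnot(length(class_names) == num_classes)
  build_network(num_classes, variant, "msc", msc, "student", class_names, seed)
}

#' Build an open-set expert network
#'
#' One expert per class group: a plain-stem MobileViT whose output layer has
#' one node per in-group class (in global class order) plus a trailing
#' `"other"` node that absorbs all out-of-group samples.
#'
#' @param group_classes Ordered character vector of in-group class names.
#' @param variant Backbone variant (the reference setup uses `"s"`).
#' @param seed Seed for weight initialization.
#' @return A `tk_model` with `length(group_classes) + 1` output nodes.
#' @export
build_expert <- function(group_classes, variant = "s", seed = 1L) {
  if (length(group_classes) == 0) {
    rlang::abort("expert group must contain at least one class")
  }
  build_network(length(group_classes) + 1L, variant, "plain", NULL, "expert",
                c(group_classes, "other"), seed)
}

#' Build a plain-stem baseline network
#'
#' The unmodified MobileViT backbone (ordinary 3x3 stride-2 stem) with a
#' `num_classes` head; the ablation reference for the multi-scale stem.
#'
#' @inheritParams build_student
#' @return A `tk_model`.
#' @export
build_baseline <- function(num_classes, variant = "xxs", class_names = NULL,
                           seed = 1L) {
  if (num_classes < 2) rlang::abort("`num_classes` must be >= 2")
  if (is.null(class_names)) class_names <- paste0("class", seq_len(num_classes))
  stopifnot(length(class_names) == num_classes)
  build_network(num_classes, variant, "plain", NULL, "baseline", class_names,
                seed)
}

#' Build the multi-scale stem in isolation
#'
#' Useful for auditing the stem (1,096 trainable parameters at the default
#' 3 -> 4+4+4+4 configuration) and for inspecting its output shape.
#'
#' @param spec A [msc_spec()].
#' @param seed Seed for weight initialization.
#' @return A `tk_model` whose only stage is the stem.
#' @export
build_msc_stem <- function(spec = msc_spec(), seed = 1L) {
  withr::with_seed(seed, {
    ctx <- new_ctx()
    arch <- list(stem = mk_msc(ctx, "stem", spec$in_channels, spec$branch_out,
                               spec$stride))
    finalize_model(ctx, arch, "stem", character(), "msc-stem", "msc", NA_integer_)
  })
}

#' Forward pass through the multi-scale stem
#'
#' @param stem A model from [build_msc_stem()].
#' @param x Input array `c(C, H, W, N)` with `C` matching the spec.
#' @return Feature array `c(sum(branch_out), H/stride, W/stride, N)`.
#' @export
multiscale_conv_forward <- function(stem, x) {
  node <- stem$arch$stem
  if (dim(x)[1] != node$children$b3$cfg$cin) {
    rlang::abort(sprintf("input has %d channels, stem expects %d",
                         dim(x)[1], node$children$b3$cfg$cin))
  }
  mod_fwd(node, x, stem, training = FALSE)$y
}

#' Count trainable parameters
#'
#' @param model A `tk_model`.
#' @return Integer count of trainable scalar parameters.
#' @examples
#' count_parameters(build_msc_stem())  # 1096
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "tk_model"))
  sum(vapply(model$meta_list,
             function(m) if (m$trainable) m$n else 0L, numeric(1)))
}

#' Parameter count in millions
#'
#' @param model A `tk_model`.
#' @param digits Decimal places (half-up rounding).
#' @return Parameter count / 1e6, rounded.
#' @export
param_millions <- function(model, digits = 2) {
  round_half_up(count_parameters(model) / 1e6, digits)
}

#' Run a model forward
#'
#' @param model A `tk_model`.
#' @param x Input array `c(3, H, W, N)` (or a `tk_dataset`).
#' @param batch_size Mini-batch size used for the forward sweep.
#' @return A `num_nodes x N` logit matrix.
#' @export
model_forward <- function(model, x, batch_size = 64L) {
  if (inherits(x, "tk_dataset")) x <- x$x
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[4]
  out <- matrix(0, model$num_nodes, n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[, idx] <- net_forward(model, x[, , , idx, drop = FALSE],
                              training = FALSE)$logits
  }
  rownames(out) <- model$class_nodes
  out
}

#' @export
print.tk_model <- function(x, ...) {
  cat(sprintf("<tk_model> role=%s variant=%s stem=%s nodes=%d params=%s\n",
              x$role, x$variant, x$stem, x$num_nodes,
              format(count_parameters(x), big.mark = ",")))
  if (length(x$class_nodes)) {
    cat("  output nodes:", paste(x$class_nodes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Save / load model checkpoints
#'
#' Checkpoints carry the weights, BN running statistics and the model
#' metadata needed to restore the network exactly.
#'
#' @param model A `tk_model`.
#' @param path File path.
#' @return `load_checkpoint()` returns the restored `tk_model`.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(params = as.list(model$params), buffers = as.list(model$buffers),
              meta_list = model$meta_list, arch = model$arch,
              role = model$role, class_nodes = model$class_nodes,
              variant = model$variant, stem = model$stem,
              input_side = model$input_side, log = model$log)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  m <- new.env(parent = emptyenv())
  m$arch <- obj$arch
  m$params <- list2env(obj$params, parent = emptyenv())
  m$buffers <- list2env(obj$buffers, parent = emptyenv())
  m$meta_list <- obj$meta_list
  m$meta <- dplyr::bind_rows(lapply(obj$meta_list, tibble::as_tibble))
  m$grads <- new.env(parent = emptyenv())
  m$vel <- new.env(parent = emptyenv())
  m$role <- obj$role
  m$class_nodes <- obj$class_nodes
  m$variant <- obj$variant
  m$stem <- obj$stem
  m$input_side <- obj$input_side
  m$num_nodes <- length(obj$class_nodes)
  m$log <- obj$log
  class(m) <- "tk_model"
  m
}
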