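# Metrics engine: confusion matrices, micro/macro precision-recall-F1,
# per-group accuracy and group gap, stratified k-fold, CV statistics,
# Grad-CAM.

#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes, in global class
#' order.
#'
#' @param truth,pred Integer label vectors (`1..K`) or factors/characters
#'   over `class_names`.
#' @param class_names Global class order (or an integer `K`).
#' @return A `tk_confusion` integer matrix with class dimnames.
#' @export
confusion_matrix <- function(truth, pred, class_names) {
  if (is.numeric(class_names) && length(class_names) == 1) {
    class_names <- paste0("class", seq_len(class_names))
  }
  K <- length(class_names)
  to_id <- function(x) {
    if (is.numeric(x)) as.integer(x) else match(as.character(x), class_names)
  }
  t_id <- to_id(truth); p_id <- to_id(pred)
  if (any(is.na(t_id)) || any(is.na(p_id)) ||
      any(t_id < 1 | t_id > K) || any(p_id < 1 | p_id > K)) {
    rlang::abort("labels outside the class set")
  }
  cm <- matrix(0L, K, K, dimnames = list(true = class_names,
                                         predicted = class_names))
  for (i in seq_along(t_id)) cm[t_id[i], p_id[i]] <- cm[t_id[i], p_id[i]] + 1L
  class(cm) <- c("tk_confusion", class(cm))
  cm
}

#' Micro (overall) accuracy
#'
#' Pooled correct over total: `100 * trace / total`, in percent.
#'
#' @param cm A confusion matrix.
#' @return Percentage (unrounded; reports round half-up to 2 decimals).
#' @export
micro_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) rlang::abort("empty confusion matrix")
  100 * sum(diag(cm)) / total
}

#' Per-class and macro precision / recall / F1
#'
#' Per-class metrics from the confusion matrix; macro values are
#' unweighted means over classes (macro F1 is the mean of per-class F1
#' values, not the harmonic mean of macro precision and recall). A class
#' that is never predicted receives precision 0 and is flagged.
#'
#' @param cm A confusion matrix.
#' @return A `tk_metrics` list: `per_class` tibble (percent), `macro`
#'   one-row tibble with `accuracy`, `precision`, `recall`, `f1`, and `n`.
#' @export
metrics_report <- function(cm) {
  if (sum(cm) == 0) rlang::abort("empty confusion matrix")
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  recall <- unname(ifelse(support == 0, 0, tp / support) * 100)
  precision <- unname(ifelse(predicted == 0, 0, tp / predicted) * 100)
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  per_class <- tibble::tibble(
    class = rownames(cm),
    n = as.integer(support),
    precision = precision, recall = recall, f1 = f1,
    never_predicted = predicted == 0
  )
  macro <- tibble::tibble(
    accuracy = micro_accuracy(cm),
    precision = mean(precision), recall = mean(recall), f1 = mean(f1)
  )
  structure(list(per_class = per_class, macro = macro, n = sum(cm)),
            class = "tk_metrics")
}

#' @export
print.tk_metrics <- function(x, ...) {
  cat(sprintf("<tk_metrics> n=%d  accuracy=%.2f  macro P/R/F1 = %.2f/%.2f/%.2f\n",
              x$n, round_half_up(x$macro$accuracy, 2),
              round_half_up(x$macro$precision, 2),
              round_half_up(x$macro$recall, 2),
              round_half_up(x$macro$f1, 2)))
  print(dplyr::mutate(x$per_class,
                      dplyr::across(c("precision", "recall", "f1"),
                                    ~ round_half_up(.x, 2))))
  invisible(x)
}

#' Per-group micro accuracy
#'
#' Micro accuracy restricted to each group's true-class rows (a sample is
#' correct iff it lands on the diagonal, regardless of which group the
#' wrong prediction fell into).
#'
#' @param cm A confusion matrix in global class order.
#' @param assignment A `tk_groups` assignment covering every class of `cm`.
#' @return A `tk_group_report` tibble: `group`, `n`, `correct`, `accuracy`
#'   (percent).
#' @export
group_accuracy <- function(cm, assignment) {
  missing <- setdiff(rownames(cm), assignment$class)
  if (length(missing)) {
    rlang::abort(sprintf("class(es) missing from assignment: %s",
                         paste(missing, collapse = ", ")))
  }
  gl <- group_classes(assignment)
  gl <- gl[lengths(gl) > 0]
  rows <- purrr::map(gl, ~ match(.x, rownames(cm)))
  out <- tibble::tibble(
    group = names(gl),
    n = purrr::map_int(rows, ~ as.integer(sum(cm[.x, ]))),
    correct = purrr::map_int(rows, ~ as.integer(sum(diag(cm)[.x])))
  )
  out$accuracy <- unname(100 * out$correct / out$n)
  class(out) <- c("tk_group_report", class(out))
  out
}

#' Group gap statistic
#'
#' Maximum pairwise difference among per-group accuracies (max minus min),
#' in percentage points, rounded half-up to 2 decimals.
#'
#' @param report A `tk_group_report` (or numeric vector of group
#'   accuracies).
#' @return Percentage points.
#' @export
group_gap <- function(report) {
  acc <- if (is.numeric(report)) report else report$accuracy
  acc <- acc[!is.na(acc)]
  if (length(acc) < 2) rlang::abort("group gap needs at least two groups")
  round_half_up(max(acc) - min(acc), 2)
}

#' Stratified k-fold partitions
#'
#' Spreads each class's samples across the folds as evenly as possible;
#' every sample appears in exactly one validation fold.
#'
#' @param labels Integer or factor class labels.
#' @param k Number of folds.
#' @param seed Seed for the within-class shuffles.
#' @return List of `k` lists with integer index vectors `train` and `val`.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  f <- factor(labels)
  sizes <- table(f)
  if (any(sizes < k)) {
    rlang::abort(sprintf("class(es) with fewer than k=%d samples: %s", k,
                         paste(names(sizes)[sizes < k], collapse = ", ")))
  }
  fold_of <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (cl in levels(f)) {
      idx <- sample(which(f == cl))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(i) {
    list(train = which(fold_of != i), val = which(fold_of == i))
  })
}

#' Cross-validation fold statistics
#'
#' Mean and population standard deviation (divisor `n`) of per-fold metric
#' values, rounded half-up to 2 decimals.
#'
#' @param values Numeric per-fold values (percent).
#' @return One-row tibble: `k`, `mean`, `sd`.
#' @export
cv_stats <- function(values) {
  if (length(values) == 0) rlang::abort("no fold values")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  tibble::tibble(k = length(values), mean = round_half_up(m, 2),
                 sd = round_half_up(s, 2))
}

#' Evaluate a model on a dataset
#'
#' @param model A `tk_model`.
#' @param data A `tk_dataset`.
#' @param batch_size Forward batch size.
#' @return A `tk_eval` list: `cm`, `metrics` and the prediction vector.
#' @export
evaluate_model <- function(model, data, batch_size = 64L) {
  logits <- model_forward(model, data, batch_size)
  pred <- max.col(t(logits), ties.method = "first")
  cm <- confusion_matrix(data$y, pred, data$class_names)
  structure(list(cm = cm, metrics = metrics_report(cm), pred = pred),
            class = "tk_eval")
}

#' @export
print.tk_eval <- function(x, ...) {
  print(x$metrics)
  invisible(x)
}

# Core Grad-CAM combination: channel weights are the spatial means of the
# gradients; the map is the ReLU of the weighted activation sum.
gradcam_combine <- function(act, grad) {
  C <- dim(act)[1]
  w <- rowMeans(matrix(grad, nrow = C))
  m <- matrix(colSums(matrix(act, nrow = C) * w), dim(act)[2], dim(act)[3])
  pmax(m, 0)
}

#' Grad-CAM heatmap
#'
#' Gradient-weighted class-activation map at a named stage: channel
#' weights are global-average-pooled gradients of the target-class logit,
#' the weighted activation sum is ReLU'd, min-max normalized and
#' bilinearly upsampled to the input size.
#'
#' @param model A `tk_model`.
#' @param image One input tensor `c(3, side, side)` (or a `tk_dataset` and
#'   `index`).
#' @param target_class Class id (or name) whose evidence is mapped.
#' @param layer Stage name; see `names(model$arch)`.
#' @param index Image index when `image` is a dataset.
#' @return `side x side` matrix in `[0, 1]`.
#' @export
gradcam_heatmap <- function(model, image, target_class, layer, index = 1L) {
  if (inherits(image, "tk_dataset")) image <- image$x[, , , index]
  stages <- names(model$arch)
  if (!layer %in% stages) {
    rlang::abort(sprintf("unknown layer '%s'; available: %s", layer,
                         paste(stages, collapse = ", ")))
  }
  if (is.character(target_class)) {
    target_class <- match(target_class, model$class_nodes)
  }
  x <- array(image, c(dim(image), 1L))
  fw <- net_forward(model, x, training = FALSE, want_cache = TRUE,
                    record_stages = TRUE)
  dlogits <- matrix(0, model$num_nodes, 1)
  dlogits[target_class, 1] <- 1
  dact <- net_backward(model, fw$caches, dlogits, stop_stage = layer)
  act <- fw$stages[[layer]]
  m <- gradcam_combine(array(act, dim(act)[1:3]), array(dact, dim(act)[1:3]))
  rng <- range(m)
  m <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
  side <- dim(image)[2]
  if (!all(dim(m) == c(side, dim(image)[3]))) {
    m <- EBImage::resize(m, w = side, h = dim(image)[3])
    m <- pmin(pmax(m, 0), 1)
  }
  m
}
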