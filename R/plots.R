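# ggplot2 displays for the main result types.

#' Plot per-class counts of a manifest
#'
#' Bar chart of training counts in global class order, colored by group
#' when an assignment is supplied; the visual long-tail check.
#'
#' @param manifest A `tk_manifest`.
#' @param assignment Optional `tk_groups` assignment.
#' @return A ggplot.
#' @export
plot_class_counts <- function(manifest, assignment = NULL) {
  df <- tibble::tibble(class = factor(manifest$class,
                                      levels = manifest$class),
                       train = manifest$train)
  if (!is.null(assignment)) {
    df$group <- assignment$group[match(df$class, assignment$class)]
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$train)) +
    ggplot2::labs(x = NULL, y = "training images") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (is.null(assignment)) {
    p + ggplot2::geom_col()
  } else {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$group))
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a confusion matrix
#'
#' @param object A `tk_confusion`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tk_confusion <- function(object, ...) {
  df <- tibble::as_tibble(as.table(unclass(object)))
  names(df) <- c("true", "predicted", "n")
  lv <- rownames(object)
  df$true <- factor(df$true, levels = rev(lv))
  df$predicted <- factor(df$predicted, levels = lv)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Training-log curves
#'
#' Loss and training accuracy per epoch for a trained model.
#'
#' @param model A trained `tk_model` (with `model$log`).
#' @return A ggplot.
#' @export
plot_training_log <- function(model) {
  if (is.null(model$log)) rlang::abort("model has no training log")
  df <- tidyr::pivot_longer(model$log[, c("epoch", "loss", "train_acc")],
                            cols = c("loss", "train_acc"),
                            names_to = "series")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Grad-CAM overlay
#'
#' @param img H x W x 3 image in `[0, 255]`.
#' @param heatmap Matrix from [gradcam_heatmap()].
#' @param alpha Overlay opacity.
#' @return A ggplot.
#' @export
plot_gradcam <- function(img, heatmap, alpha = 0.5) {
  H <- dim(img)[1]; W <- dim(img)[2]
  gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / (3 * 255)
  cam <- alpha * heatmap
  df <- tibble::tibble(
    x = rep(seq_len(W), each = H), y = rep(rev(seq_len(H)), W),
    col = grDevices::rgb(pmin(1, as.vector(gray + cam)),
                         as.vector(gray * (1 - cam)),
                         as.vector(gray * (1 - cam))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$col)) +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
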