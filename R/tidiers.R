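# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained model
#'
#' Returns the per-epoch training log (loss, learning rates, training
#' accuracy) as a tibble; for an untrained model, the per-parameter
#' inventory.
#'
#' @param x A `tk_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tk_model <- function(x, ...) {
  if (!is.null(x$log)) return(x$log)
  x$meta
}

#' One-row model summary
#'
#' @param x A `tk_model`.
#' @param ... Unused.
#' @return Tibble with role, variant, stem, output nodes, parameter count
#'   (raw and millions) and, when trained, the final loss and training
#'   accuracy.
#' @export
glance.tk_model <- function(x, ...) {
  out <- tibble::tibble(
    role = x$role, variant = x$variant, stem = x$stem,
    num_nodes = x$num_nodes,
    parameters = count_parameters(x),
    parameters_m = param_millions(x)
  )
  if (!is.null(x$log)) {
    out$final_loss <- utils::tail(x$log$loss, 1)
    out$final_train_acc <- utils::tail(x$log$train_acc, 1)
  }
  out
}

#' Tidy a metrics report
#'
#' @param x A `tk_metrics`.
#' @param ... Unused.
#' @return The per-class tibble (percent, half-up rounded to 2 decimals).
#' @export
tidy.tk_metrics <- function(x, ...) {
  dplyr::mutate(x$per_class,
                dplyr::across(c("precision", "recall", "f1"),
                              ~ round_half_up(.x, 2)))
}

#' @rdname tidy.tk_metrics
#' @export
glance.tk_metrics <- function(x, ...) {
  tibble::tibble(n = x$n,
                 accuracy = round_half_up(x$macro$accuracy, 2),
                 macro_precision = round_half_up(x$macro$precision, 2),
                 macro_recall = round_half_up(x$macro$recall, 2),
                 macro_f1 = round_half_up(x$macro$f1, 2))
}

#' Tidy an evaluation
#'
#' @param x A `tk_eval`.
#' @param ... Unused.
#' @return Per-class metrics tibble.
#' @export
tidy.tk_eval <- function(x, ...) tidy(x$metrics)

#' @rdname tidy.tk_eval
#' @export
glance.tk_eval <- function(x, ...) glance(x$metrics)
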