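# Reference measurements from the greenhouse tomato cultivation-stage
# study whose methodology this package implements. They serve two roles:
# the count table is the canonical long-tailed class profile (and the
# template for the synthetic generator), and the reported per-class /
# per-fold values are the inputs from which the metrics engine
# reconstructs the study's printed aggregates.

ref_csv <- function(name) {
  readr::read_csv(system.file("extdata", name, package = "tailkd",
                              mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' Cultivation-stage image counts
#'
#' Per-class raw counts, the 1:1 stratified train/test split and the
#' post-augmentation training counts for the nine greenhouse tomato
#' cultivation stages (1,999 images in total).
#'
#' @return A `tk_manifest` tibble in global class order.
#' @export
stage_counts <- function() {
  as_manifest(ref_csv("cultivation_stage_counts.csv"))
}

#' Reported per-class recall of the distilled student
#'
#' Per-class recall (%) of the distilled MSC-MobileViT on the held-out
#' test set, with each class's head/balance/tail group.
#'
#' @return A tibble with `class`, `group`, `recall`, in global class order.
#' @export
reported_per_class_recall <- function() {
  ref_csv("reported_per_class_recall.csv")
}

#' Reported per-group accuracies
#'
#' Within-group micro accuracy (%) of the experts, the expert ensemble,
#' the plain student and the distilled student on the head, balance and
#' tail groups.
#'
#' @return A tibble with `model`, `head`, `balance`, `tail`.
#' @export
reported_group_accuracy <- function() {
  ref_csv("reported_group_accuracy.csv")
}

#' Reported overall model metrics
#'
#' Accuracy, macro precision/recall/F1 (%) of each expert on its relabeled
#' test set and of the ensemble, plain student and distilled student on
#' all classes.
#'
#' @return A tibble with `model`, `accuracy`, `precision`, `recall`, `f1`.
#' @export
reported_model_metrics <- function() {
  ref_csv("reported_model_metrics.csv")
}

#' Reported five-fold cross-validation values
#'
#' Per-fold accuracy/precision/recall/F1 (%) of the baseline and the
#' distilled student under five-fold stratified cross-validation.
#'
#' @return A tibble with `fold`, `model` and the four metric columns.
#' @export
reported_cv_folds <- function() {
  ref_csv("reported_cv_folds.csv")
}
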