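# Dataset manifests, the stratified 1:1 split, head/balance/tail grouping
# and augmentation planning.

#' Construct a dataset manifest
#'
#' A manifest records, per class, the raw image count, its train/test
#' split, and the post-augmentation training count. Classes are kept in
#' the global class order: descending original training count, ties broken
#' by first appearance. All later stages (grouping, expert node ordering,
#' logit splicing) rely on this order.
#'
#' @param df A data frame with columns `class`, `raw`, `train`, `test` and
#'   optionally `train_aug` (defaults to `train`).
#' @return A `tk_manifest` tibble in global class order.
#' @export
as_manifest <- function(df) {
  need <- c("class", "raw", "train", "test")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    rlang::abort(sprintf("manifest is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  df <- tibble::as_tibble(df)
  if (!"train_aug" %in% names(df)) df$train_aug <- df$train
  df <- dplyr::select(df, "class", "raw", "train", "train_aug", "test")
  if (anyDuplicated(df$class)) {
    rlang::abort("duplicate class names in manifest")
  }
  for (col in c("raw", "train", "train_aug", "test")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))   # empty CSVs parse as logical
    check_counts(df[[col]], paste0("column '", col, "'"))
    df[[col]] <- as.integer(df[[col]])
  }
  bad <- df$train + df$test != df$raw
  if (any(bad)) {
    rlang::abort(sprintf("train + test != raw for class(es): %s",
                         paste(df$class[bad], collapse = ", ")))
  }
  if (any(df$train_aug < df$train)) {
    rlang::abort("train_aug must be >= train for every class")
  }
  df <- df[order(-df$train), , drop = FALSE]   # stable: ties keep file order
  class(df) <- c("tk_manifest", class(df))
  df
}

#' Read a manifest CSV
#'
#' @param path Path to a UTF-8 CSV with header columns `class`, `raw`,
#'   `train`, `test` (plus optional `train_aug`).
#' @return A `tk_manifest` tibble, sorted into global class order.
#' @export
load_manifest <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_manifest(df)
}

#' Write a manifest CSV
#'
#' @param manifest A `tk_manifest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(tibble::as_tibble(manifest)[, c("class", "raw", "train",
                                                   "train_aug", "test")],
                   path)
  invisible(path)
}

#' Manifest column totals
#'
#' Totals are always the column sums of the manifest (a stated headline
#' total that disagrees with its own per-class table is reported as the
#' column sum, not forced).
#'
#' @param manifest A `tk_manifest`.
#' @return A one-row tibble with `raw`, `train`, `train_aug`, `test` totals
#'   and the class count.
#' @export
manifest_totals <- function(manifest) {
  tibble::tibble(
    n_classes = nrow(manifest),
    raw = sum(manifest$raw),
    train = sum(manifest$train),
    train_aug = sum(manifest$train_aug),
    test = sum(manifest$test)
  )
}

#' Stratified 1:1 train/test split counts
#'
#' Per class, the training side receives `ceiling(raw / 2)` images and the
#' test side the rest, so odd counts put the extra image in the training
#' set. The concrete assignment of images is a seeded permutation; see
#' [split_indices()].
#'
#' @param df A data frame with columns `class` and `raw`.
#' @return The input with `train` and `test` columns added.
#' @export
stratified_split <- function(df) {
  check_counts(df$raw, "`raw`")
  df <- tibble::as_tibble(df)
  df$train <- as.integer(ceiling(df$raw / 2))
  df$test <- as.integer(df$raw - df$train)
  df
}

#' Seeded assignment of items to the two split halves
#'
#' @param n Number of items in a class.
#' @param seed Integer seed; the same seed always reproduces the same
#'   assignment.
#' @return A list with integer index vectors `train` (length
#'   `ceiling(n/2)`) and `test`.
#' @export
split_indices <- function(n, seed) {
  if (n == 0) return(list(train = integer(), test = integer()))
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  k <- ceiling(n / 2)
  list(train = sort(perm[seq_len(k)]),
       test = sort(perm[setdiff(seq_len(n), seq_len(k))]))
}

#' Assign classes to head / balance / tail groups
#'
#' Grouping uses *original* (pre-augmentation) training counts: a class is
#' Head when `train >= head_min`, Balance when
#' `balance_min <= train < head_min`, otherwise Tail. The defaults 200/50
#' reproduce the reference study's 2/3/4 partition of the nine
#' cultivation stages.
#'
#' @param manifest A `tk_manifest` (or data frame with `class`, `train`).
#' @param head_min Minimum training count for the Head group.
#' @param balance_min Minimum training count for the Balance group.
#' @return A `tk_groups` tibble (`class`, `train`, `group`) in global class
#'   order.
#' @export
assign_groups <- function(manifest, head_min = 200L, balance_min = 50L) {
  if (nrow(manifest) == 0) rlang::abort("cannot group an empty manifest")
  if (!(head_min > balance_min && balance_min >= 1)) {
    rlang::abort("need head_min > balance_min >= 1")
  }
  df <- tibble::tibble(class = manifest$class, train = manifest$train)
  df$group <- factor(
    dplyr::case_when(
      df$train >= head_min ~ "Head",
      df$train >= balance_min ~ "Balance",
      TRUE ~ "Tail"
    ),
    levels = c("Head", "Balance", "Tail")
  )
  class(df) <- c("tk_groups", class(df))
  df
}

#' Per-group ordered class lists
#'
#' @param groups A `tk_groups` assignment.
#' @return Named list `Head`/`Balance`/`Tail` of class-name vectors, each in
#'   global class order; their concatenation reproduces the global order.
#' @export
group_classes <- function(groups) {
  lapply(split(groups$class, groups$group), as.character)
}

#' Plan augmentation multipliers for small classes
#'
#' Classes with fewer than `small_class_threshold` training images receive
#' `m = ceiling(floor_target / n)` copies of each image (capped at 8: the
#' original plus at most one copy per distinct transform); larger classes
#' are left untouched. With the defaults this reproduces the reference
#' post-augmentation counts 90/104/96/114/96 for training counts
#' 30/26/16/57/12.
#'
#' @param manifest A `tk_manifest` (or data frame with `class`, `train`).
#' @param small_class_threshold Classes below this training count are
#'   augmented.
#' @param floor_target Approximate post-augmentation target count.
#' @param seed Seed for drawing each class's transforms.
#' @return A tibble with `class`, `train`, `multiplier`, `post_count` and a
#'   `transforms` list-column holding the `m - 1` transform names drawn
#'   without replacement from the seven-transform list.
#' @export
plan_augmentation <- function(manifest, small_class_threshold = 100L,
                              floor_target = 90L, seed = 1L) {
  n <- manifest$train
  if (any(n == 0 & n < small_class_threshold)) {
    rlang::abort("cannot augment a class with zero training images")
  }
  m <- ifelse(n < small_class_threshold, pmin(ceiling(floor_target / n), 8L), 1L)
  seeds <- seed_stream(seed, length(n))
  transforms <- purrr::map2(m, seeds, function(mi, si) {
    if (mi <= 1) character() else
      withr::with_seed(si, sample(transform_names(), mi - 1L))
  })
  tibble::tibble(
    class = manifest$class,
    train = as.integer(n),
    multiplier = as.integer(m),
    post_count = as.integer(n * m),
    transforms = transforms
  )
}

#' @export
print.tk_manifest <- function(x, ...) {
  cat("<tk_manifest> ", nrow(x), " classes (global order: descending train count)\n",
      sep = "")
  NextMethod()
}
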