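# In-memory datasets: normalized tensors plus integer labels.

#' Construct a dataset
#'
#' @param x Array `c(3, side, side, N)` of normalized image tensors.
#' @param y Integer labels, `1 .. length(class_names)`.
#' @param class_names Class label per output node.
#' @return A `tk_dataset`.
#' @export
tk_dataset <- function(x, y, class_names) {
  stopifnot(length(dim(x)) == 4, dim(x)[4] == length(y))
  if (length(y) && (min(y) < 1 || max(y) > length(class_names))) {
    rlang::abort("labels out of range of `class_names`")
  }
  structure(list(x = x, y = as.integer(y), class_names = class_names),
            class = "tk_dataset")
}

#' @export
print.tk_dataset <- function(x, ...) {
  cat(sprintf("<tk_dataset> %d images (%dx%d), %d classes\n",
              length(x$y), dim(x$x)[2], dim(x$x)[3], length(x$class_names)))
  print(table(factor(x$class_names[x$y], levels = x$class_names)))
  invisible(x)
}

#' Pack raw images into a dataset
#'
#' Applies [resize_normalize()] to each image and stacks the results into
#' the model input layout.
#'
#' @param imgs List of H x W x 3 arrays in `[0, 255]`.
#' @param labels Integer labels parallel to `imgs`.
#' @param class_names Class label vector.
#' @param side Model input side.
#' @param mean,std Per-channel normalization constants (defaults center the
#'   unit scale at zero).
#' @return A `tk_dataset`.
#' @export
pack_images <- function(imgs, labels, class_names, side = 64L,
                        mean = c(0.5, 0.5, 0.5), std = c(0.5, 0.5, 0.5)) {
  n <- length(imgs)
  x <- array(0, c(3L, side, side, n))
  for (i in seq_len(n)) {
    x[, , , i] <- image_to_tensor(resize_normalize(imgs[[i]], side, mean, std))
  }
  tk_dataset(x, labels, class_names)
}

#' Load a folder-per-class image tree as a dataset
#'
#' @param root Directory with one subdirectory of PNGs per class.
#' @param classes Class order (defaults to sorted subdirectory names; pass
#'   the manifest's class column to impose the global order).
#' @param side Model input side.
#' @param mean,std Normalization constants.
#' @return A `tk_dataset`.
#' @export
dataset_from_dir <- function(root, classes = NULL, side = 64L,
                             mean = c(0.5, 0.5, 0.5),
                             std = c(0.5, 0.5, 0.5)) {
  if (is.null(classes)) classes <- sort(list.dirs(root, recursive = FALSE,
                                                  full.names = FALSE))
  imgs <- list(); labels <- integer()
  for (i in seq_along(classes)) {
    files <- list.files(file.path(root, classes[i]), pattern = "\\.png$",
                        full.names = TRUE)
    for (f in files) imgs[[length(imgs) + 1L]] <- read_image(f)
    labels <- c(labels, rep(i, length(files)))
  }
  pack_images(imgs, labels, classes, side, mean, std)
}

#' Render, split and (optionally) augment a synthetic experiment in memory
#'
#' Runs the data side of the pipeline without touching disk: renders the
#' configured class counts, performs the seeded stratified 1:1 split,
#' applies the augmentation plan to the training half, and packs both
#' halves into datasets.
#'
#' @param cfg A [synthetic_config()].
#' @param augment Apply the small-class augmentation plan to the training
#'   split.
#' @param small_class_threshold,floor_target Augmentation plan settings
#'   (see [plan_augmentation()]); scale these with the count profile.
#' @param seed Seed for split assignment and augmentation draws.
#' @return List with `manifest` (`tk_manifest`), `plan`, `train` and `test`
#'   datasets.
#' @export
prepare_experiment_data <- function(cfg, augment = TRUE,
                                    small_class_threshold = 13L,
                                    floor_target = 12L, seed = 1L) {
  cls <- names(cfg$counts)
  seeds <- seed_stream(seed, length(cls) + 1L)
  split_tbl <- stratified_split(tibble::tibble(class = cls,
                                               raw = as.integer(cfg$counts)))
  manifest <- as_manifest(split_tbl)
  plan <- plan_augmentation(manifest, small_class_threshold, floor_target,
                            seed = seeds[length(cls) + 1L])
  train_imgs <- list(); train_y <- integer()
  test_imgs <- list(); test_y <- integer()
  # index classes in global (manifest) order so labels match the class order
  for (i in seq_len(nrow(manifest))) {
    ci <- match(manifest$class[i], cls)
    imgs <- render_class_stack(cfg, ci, cfg$counts[ci])
    sp <- split_indices(length(imgs), seeds[ci])
    tr <- imgs[sp$train]
    if (augment) {
      row <- plan[plan$class == manifest$class[i], ]
      tfs <- row$transforms[[1]]
      if (length(tfs)) {
        tseeds <- seed_stream(seeds[ci] + 1L, length(tr))
        aug <- list()
        for (j in seq_along(tr)) {
          for (k in seq_along(tfs)) {
            sp2 <- transform_spec(tfs[k], seed = tseeds[j] %% 1000000L + k)
            aug[[length(aug) + 1L]] <- apply_transform(tr[[j]], sp2)
          }
        }
        tr <- c(tr, aug)
      }
    }
    train_imgs <- c(train_imgs, tr)
    train_y <- c(train_y, rep(i, length(tr)))
    test_imgs <- c(test_imgs, imgs[sp$test])
    test_y <- c(test_y, rep(i, length(sp$test)))
  }
  list(manifest = manifest, plan = plan,
       train = pack_images(train_imgs, train_y, manifest$class, cfg$side),
       test = pack_images(test_imgs, test_y, manifest$class, cfg$side))
}

dataset_subset <- function(ds, idx) {
  tk_dataset(ds$x[, , , idx, drop = FALSE], ds$y[idx], ds$class_names)
}
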