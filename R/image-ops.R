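# The seven augmentation transforms and standard preprocessing. Images are
# H x W x 3 numeric arrays on the 8-bit scale [0, 255].

#' The seven augmentation transform names
#'
#' 90-degree rotation (counter-clockwise), 180-degree rotation, contrast
#' reduction, contrast enhancement, horizontal mirror flip, Gaussian blur
#' and Gaussian noise addition.
#'
#' @return Character vector of the seven transform names.
#' @export
transform_names <- function() {
  c("rot90", "rot180", "contrast_down", "contrast_up", "hflip",
    "gauss_blur", "gauss_noise")
}

#' Transform specification
#'
#' @param name One of [transform_names()].
#' @param contrast_factor Scaling factor about mid-gray for the contrast
#'   transforms (defaults: 0.6 down, 1.4 up).
#' @param blur_sigma Gaussian blur standard deviation in pixels.
#' @param noise_sigma Gaussian noise standard deviation on the 8-bit scale.
#' @param seed Seed making `gauss_noise` deterministic.
#' @return A `tk_transform` list.
#' @export
transform_spec <- function(name, contrast_factor = NULL, blur_sigma = 1,
                           noise_sigma = 10, seed = 1L) {
  if (!name %in% transform_names()) {
    rlang::abort(sprintf("unknown transform '%s' (expected one of: %s)",
                         name, paste(transform_names(), collapse = ", ")))
  }
  if (is.null(contrast_factor)) {
    contrast_factor <- switch(name, contrast_down = 0.6, contrast_up = 1.4, 1)
  }
  structure(list(name = name, contrast_factor = contrast_factor,
                 blur_sigma = blur_sigma, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "tk_transform")
}

check_image <- function(img) {
  if (length(dim(img)) != 3 || dim(img)[3] != 3) {
    rlang::abort("image must be an H x W x 3 array")
  }
  invisible(img)
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

#' Apply an augmentation transform
#'
#' Geometric transforms (`rot90`, `rot180`, `hflip`) permute pixels
#' losslessly; photometric transforms clamp to the 8-bit range;
#' `gauss_noise` is deterministic given the spec's seed.
#'
#' @param img H x W x 3 array, values in `[0, 255]`.
#' @param t A [transform_spec()] or a transform name.
#' @return The transformed image, same channel count.
#' @export
apply_transform <- function(img, t) {
  if (is.character(t)) t <- transform_spec(t)
  check_image(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  switch(t$name,
    rot90 = aperm(img, c(2, 1, 3))[W:1, , , drop = FALSE],   # counter-clockwise
    rot180 = img[H:1, W:1, , drop = FALSE],
    hflip = img[, W:1, , drop = FALSE],
    contrast_down = ,
    contrast_up = clamp255(128 + (img - 128) * t$contrast_factor),
    gauss_blur = clamp255(EBImage::gblur(img, sigma = t$blur_sigma)),
    gauss_noise = clamp255(
      img + withr::with_seed(t$seed,
                             array(stats::rnorm(length(img), 0, t$noise_sigma),
                                   dim(img))))
  )
}

#' Read / write an 8-bit PNG image
#'
#' @param path File path.
#' @return `read_image()` returns an H x W x 3 array in `[0, 255]`;
#'   grayscale images are replicated to 3 channels and alpha is dropped.
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2) x <- array(rep(x, 3), c(dim(x), 3))
  if (dim(x)[3] == 4) x <- x[, , 1:3, drop = FALSE]
  x * 255
}

#' @rdname read_image
#' @param img H x W x 3 array in `[0, 255]`.
#' @export
write_image <- function(img, path) {
  png::writePNG(clamp255(img) / 255, path)
  invisible(path)
}

#' Augment all images of one class directory
#'
#' Each original image gains `multiplier - 1` augmented copies, one per
#' selected transform, written next to the originals as
#' `<stem>__<transform>.png`, so the directory ends with
#' `n * multiplier` files.
#'
#' @param dir Class directory of PNG files.
#' @param multiplier Per-class multiplier `m >= 1`.
#' @param transforms Character vector of `m - 1` transform names; drawn
#'   (seeded, without replacement) from the seven-transform list when `NULL`.
#' @param seed Seed for transform selection and noise.
#' @return Tibble of written files, invisibly.
#' @export
augment_class_folder <- function(dir, multiplier, transforms = NULL,
                                 seed = 1L) {
  files <- list.files(dir, pattern = "\\.png$", full.names = TRUE)
  if (multiplier <= 1) return(invisible(tibble::tibble(file = character())))
  if (length(files) == 0) {
    rlang::abort(sprintf("directory '%s' has no PNG images to augment", dir))
  }
  if (is.null(transforms)) {
    transforms <- withr::with_seed(as.integer(seed),
                                   sample(transform_names(), multiplier - 1L))
  }
  stopifnot(length(transforms) == multiplier - 1)
  seeds <- seed_stream(seed, length(files))
  written <- character()
  for (i in seq_along(files)) {
    img <- read_image(files[i])
    stem <- sub("\\.png$", "", basename(files[i]))
    for (j in seq_along(transforms)) {
      sp <- transform_spec(transforms[j], seed = seeds[i] %% 1000000L + j)
      out <- file.path(dir, paste0(stem, "__", transforms[j], ".png"))
      write_image(apply_transform(img, sp), out)
      written <- c(written, out)
    }
  }
  invisible(tibble::tibble(file = written))
}

#' Resize and normalize an image for model input
#'
#' Bilinear resize to `side x side`, scale to `[0, 1]`, then standardize
#' each channel by `(x - mean) / std`. The defaults are the ImageNet
#' constants; pass `mean = c(0, 0, 0)`, `std = c(1, 1, 1)` for identity
#' normalization.
#'
#' @param img H x W x 3 array in `[0, 255]`.
#' @param side Output side length in pixels.
#' @param mean,std Per-channel normalization constants on the `[0, 1]` scale.
#' @return A `side x side x 3` numeric array.
#' @export
resize_normalize <- function(img, side = 224L,
                             mean = c(0.485, 0.456, 0.406),
                             std = c(0.229, 0.224, 0.225)) {
  check_image(img)
  if (side <= 0) rlang::abort("`side` must be positive")
  if (dim(img)[1] != side || dim(img)[2] != side) {
    img <- EBImage::resize(img, w = side, h = side)
  }
  x <- img / 255
  for (k in 1:3) x[, , k] <- (x[, , k] - mean[k]) / std[k]
  x
}

# H x W x 3 -> internal (C, H, W) tensor layout
image_to_tensor <- function(img) aperm(img, c(3, 1, 2))
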