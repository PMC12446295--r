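# Synthetic long-tailed image generator. Each class is a unique
# (shape, scale, texture-frequency, hue) motif rendered at jittered
# position/size over a noisy background, so label information is carried
# both by global structure (shape, size) and by local detail (texture
# frequency) -- the multi-scale situation the architecture targets.

#' Long-tailed class-count profile
#'
#' The canonical nine-class raw-count profile
#' (608/589/263/260/113/59/51/32/24 in global class order), optionally
#' scaled down by an integer divisor with per-class `ceiling()`.
#'
#' @param divisor Integer scale-down factor (1 = full size).
#' @return Named integer vector of per-class raw counts.
#' @export
synthetic_profile <- function(divisor = 1L) {
  raw <- c(idle_period = 608L, mid_production = 589L, late_production = 263L,
           seedling_pulling = 260L, planting = 113L,
           substrate_placement = 59L, hole_opening = 51L,
           substrate_soaking = 32L, early_production = 24L)
  stats::setNames(as.integer(ceiling(raw / divisor)), names(raw))
}

#' Per-class rendering styles
#'
#' Assigns each class a unique (shape, scale, texture frequency, hue)
#' combination. Shapes are drawn from disc/square/ring/cross/stripes at
#' two spatial scales.
#'
#' @param n_classes Number of classes (at most 10).
#' @return A tibble with columns `class_id`, `shape`, `scale`, `freq`, `hue`.
#' @export
class_styles <- function(n_classes = 9L) {
  shapes <- c("disc", "square", "ring", "cross", "stripes")
  styles <- tibble::tibble(
    class_id = seq_len(10L),
    shape = rep(shapes, 2L),
    scale = rep(c("large", "small"), each = 5L),
    freq = c(0, 2, 1, 3, 4, 6, 5, 8, 7, 9),
    hue = seq(0, 0.9, by = 0.1)
  )
  if (n_classes > nrow(styles)) {
    rlang::abort("at most 10 distinct class styles are defined")
  }
  styles[seq_len(n_classes), ]
}

#' Synthetic dataset configuration
#'
#' @param counts Named per-class raw counts (default: the long-tailed
#'   profile scaled down by 8, the desk-scale study condition).
#' @param side Image side in pixels (>= 16).
#' @param noise_sd Background noise standard deviation (8-bit scale).
#' @param jitter Randomize motif position/size per image.
#' @param seed Master seed; every image's randomness derives from it.
#' @return A `tk_synth_config` list.
#' @export
synthetic_config <- function(counts = synthetic_profile(8L), side = 64L,
                             noise_sd = 8, jitter = TRUE, seed = 1L) {
  if (any(counts <= 0)) rlang::abort("class counts must be positive")
  if (side < 16) rlang::abort("`side` must be >= 16")
  if (is.null(names(counts))) {
    names(counts) <- sprintf("class%02d", seq_along(counts))
  }
  structure(list(counts = counts, side = as.integer(side),
                 noise_sd = noise_sd, jitter = jitter,
                 seed = as.integer(seed),
                 styles = class_styles(length(counts))),
            class = "tk_synth_config")
}

#' Render one synthetic image
#'
#' Deterministic given `(style, seed)`: the same pair always produces the
#' identical array. With `noise_sd = 0` and `jitter = FALSE` the motif is
#' centered with a fixed radius, and for a texture frequency of 0 the
#' center pixel equals the class hue converted to RGB exactly.
#'
#' @param style One row of [class_styles()] (list or one-row data frame).
#' @param side Image side in pixels.
#' @param seed Per-image seed.
#' @param noise_sd Background noise sd; 0 for a clean background.
#' @param jitter Randomize motif position/size.
#' @return H x W x 3 array in `[0, 255]`.
#' @export
render_image <- function(style, side = 64L, seed = 1L, noise_sd = 8,
                         jitter = TRUE) {
  withr::with_seed(as.integer(seed), {
    base_r <- side * if (style$scale == "large") 0.32 else 0.13
    cx <- side / 2; cy <- side / 2; r <- base_r
    if (jitter) {
      cx <- cx + stats::runif(1, -side / 8, side / 8)
      cy <- cy + stats::runif(1, -side / 8, side / 8)
      r <- r * stats::runif(1, 0.85, 1.15)
    }
    xs <- matrix(rep(seq_len(side), each = side), side)   # column index
    ys <- matrix(rep(seq_len(side), side), side)          # row index
    dx <- xs - cx; dy <- ys - cy
    dist <- sqrt(dx^2 + dy^2)
    mask <- switch(style$shape,
      disc = dist <= r,
      square = pmax(abs(dx), abs(dy)) <= r,
      ring = dist <= r & dist >= 0.55 * r,
      cross = (abs(dx) <= r / 3 & abs(dy) <= r) |
              (abs(dy) <= r / 3 & abs(dx) <= r),
      stripes = pmax(abs(dx), abs(dy)) <= r & sin(pi * 3 * dy / r) > 0
    )
    tex <- if (style$freq > 0) {
      0.7 + 0.3 * sin(2 * pi * style$freq * (dx + dy) / (2 * r))^2
    } else {
      matrix(1, side, side)
    }
    col <- grDevices::col2rgb(grDevices::hsv(style$hue, 0.75, 0.95))[, 1]
    img <- array(stats::rnorm(side * side * 3, 110, noise_sd),
                 c(side, side, 3))
    for (k in 1:3) {
      ch <- img[, , k]
      ch[mask] <- (col[k] * tex)[mask]
      img[, , k] <- ch
    }
    clamp255(img)
  })
}

render_class_stack <- function(cfg, class_idx, n) {
  seeds <- seed_stream(cfg$seed + class_idx, n)
  style <- as.list(cfg$styles[class_idx, ])
  lapply(seq_len(n), function(j) {
    render_image(style, cfg$side, seeds[j], cfg$noise_sd, cfg$jitter)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes one directory of PNGs per class under `out_dir` plus a
#' `manifest.csv` (`class,raw,train,test`, split counts following the
#' ceiling rule) consistent with the directory contents. Regeneration with
#' the same configuration is byte-identical.
#'
#' @param cfg A [synthetic_config()].
#' @param out_dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return The manifest tibble, invisibly.
#' @export
generate_dataset <- function(cfg, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite) {
    rlang::abort(sprintf("'%s' exists and is not empty (use overwrite = TRUE)",
                         out_dir))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cls <- names(cfg$counts)
  for (i in seq_along(cls)) {
    cdir <- file.path(out_dir, cls[i])
    dir.create(cdir, showWarnings = FALSE)
    imgs <- render_class_stack(cfg, i, cfg$counts[i])
    for (j in seq_along(imgs)) {
      write_image(imgs[[j]], file.path(cdir, sprintf("img_%04d.png", j)))
    }
  }
  manifest <- stratified_split(tibble::tibble(class = cls,
                                              raw = as.integer(cfg$counts)))
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}
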