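make_img <- function(side = 8, seed = 1) {
  withr::with_seed(seed, array(runif(side * side * 3, 0, 255),
                               c(side, side, 3)))
}

test_that("geometric transforms satisfy their symmetries", {
  img <- make_img()
  expect_equal(apply_transform(apply_transform(img, "rot90"), "rot90"),
               apply_transform(img, "rot180"))
  expect_equal(apply_transform(apply_transform(img, "hflip"), "hflip"), img)
  expect_equal(apply_transform(apply_transform(img, "rot180"), "rot180"), img)
})

test_that("rot90 is the counter-clockwise index mapping", {
  # 2x2 image [[a,b],[c,d]] -> [[b,d],[a,c]], derived by brute-force
  # index enumeration
  img <- array(0, c(2, 2, 3))
  img[1, 1, ] <- 1; img[1, 2, ] <- 2   # a, b
  img[2, 1, ] <- 3; img[2, 2, ] <- 4   # c, d
  r <- apply_transform(img, "rot90")
  expect_equal(r[1, 1, 1], 2)  # b
  expect_equal(r[1, 2, 1], 4)  # d
  expect_equal(r[2, 1, 1], 1)  # a
  expect_equal(r[2, 2, 1], 3)  # c
})

test_that("geometric transforms preserve the pixel multiset, photometric the shape", {
  img <- make_img()
  for (tf in c("rot90", "rot180", "hflip")) {
    expect_equal(sort(as.vector(apply_transform(img, tf))),
                 sort(as.vector(img)), info = tf)
  }
  for (tf in c("contrast_down", "contrast_up", "gauss_blur", "gauss_noise")) {
    out <- apply_transform(img, tf)
    expect_equal(dim(out), dim(img), info = tf)
    expect_true(all(out >= 0 & out <= 255), info = tf)
  }
})

test_that("contrast scales about mid-gray and clamps", {
  img <- array(128, c(4, 4, 3))
  expect_equal(apply_transform(img, "contrast_down"), img)
  bright <- array(250, c(4, 4, 3))
  up <- apply_transform(bright, "contrast_up")
  expect_true(all(up == 255))
})

test_that("gaussian noise is deterministic given the spec seed", {
  img <- make_img()
  sp <- transform_spec("gauss_noise", seed = 11)
  expect_identical(apply_transform(img, sp), apply_transform(img, sp))
  sp2 <- transform_spec("gauss_noise", seed = 12)
  expect_false(identical(apply_transform(img, sp),
                         apply_transform(img, sp2)))
})

test_that("unknown transform names are rejected", {
  expect_error(transform_spec("vflip"), "unknown transform")
})

test_that("resize_normalize resizes bilinearly and standardizes channels", {
  img <- make_img(side = 8)
  out <- resize_normalize(img, side = 4, mean = c(0, 0, 0), std = c(1, 1, 1))
  expect_equal(dim(out), c(4, 4, 3))
  # constant image stays constant and equals (v/255 - mean)/std
  cimg <- array(100, c(6, 6, 3))
  out <- resize_normalize(cimg, side = 3, mean = c(0.2, 0.2, 0.2),
                          std = c(0.5, 0.5, 0.5))
  expect_equal(as.vector(out), rep((100 / 255 - 0.2) / 0.5, 27),
               tolerance = 1e-8)
  # same-size input with identity normalization is just pixels/255
  out <- resize_normalize(img, side = 8, mean = c(0, 0, 0), std = c(1, 1, 1))
  expect_equal(out, img / 255)
  expect_error(resize_normalize(img, side = 0), "positive")
})

test_that("augment_class_folder writes n * m deterministic files", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "cls"))
  cfg <- synthetic_config(counts = c(cls = 4L), side = 16L, seed = 3)
  imgs <- tailkd:::render_class_stack(cfg, 1, 4)
  for (j in seq_along(imgs)) {
    write_image(imgs[[j]], file.path(root, "cls", sprintf("im%d.png", j)))
  }
  augment_class_folder(file.path(root, "cls"), multiplier = 3,
                       transforms = c("rot90", "gauss_noise"), seed = 5)
  files <- list.files(file.path(root, "cls"))
  expect_length(files, 12)   # 4 originals * 3
  expect_length(grep("__rot90\\.png$", files), 4)
  expect_length(grep("__gauss_noise\\.png$", files), 4)

  # m = 1 leaves the directory untouched
  before <- list.files(file.path(root, "cls"))
  augment_class_folder(file.path(root, "cls"), multiplier = 1)
  expect_identical(list.files(file.path(root, "cls")), before)

  # fixed seed -> byte-identical outputs
  dir.create(file.path(root, "c2")); dir.create(file.path(root, "c3"))
  for (d in c("c2", "c3")) {
    for (j in 1:3) {
      write_image(imgs[[j]], file.path(root, d, sprintf("im%d.png", j)))
    }
    augment_class_folder(file.path(root, d), multiplier = 2, seed = 9)
  }
  f2 <- sort(list.files(file.path(root, "c2"), full.names = TRUE))
  f3 <- sort(list.files(file.path(root, "c3"), full.names = TRUE))
  for (i in seq_along(f2)) {
    expect_identical(readBin(f2[i], "raw", 1e6), readBin(f3[i], "raw", 1e6))
  }

  dir.create(file.path(root, "empty"))
  expect_error(augment_class_folder(file.path(root, "empty"), 2), "no PNG")
})
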