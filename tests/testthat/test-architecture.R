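test_that("multi-scale stem yields half-resolution concatenated features", {
  stem <- build_msc_stem(msc_spec(3L, c(4L, 4L, 4L, 4L)), seed = 2)
  x <- withr::with_seed(1, array(rnorm(3 * 224 * 224), c(3, 224, 224, 1)))
  y <- multiscale_conv_forward(stem, x)
  expect_equal(dim(y), c(16, 112, 112, 1))
  x64 <- withr::with_seed(1, array(rnorm(3 * 64 * 64 * 2), c(3, 64, 64, 2)))
  expect_equal(dim(multiscale_conv_forward(stem, x64)), c(16, 32, 32, 2))
  # all four branches share spatial dims for any even side
  x10 <- array(0, c(3, 10, 10, 1))
  expect_equal(dim(multiscale_conv_forward(stem, x10)), c(16, 5, 5, 1))
  expect_error(multiscale_conv_forward(stem, array(0, c(4, 8, 8, 1))),
               "channels")
})

test_that("stem parameter count matches the hand-derived 1,096", {
  # per branch (convs bias-free, BN affine): 3*4+8 | (3*4+8)+(4*4*9+8) |
  # 3*4*25+8 | 3*4*49+8  ->  20+172+308+596 = 1096
  expect_equal(count_parameters(build_msc_stem()), 1096L)
})

test_that("student and plain-stem baseline both audit at 0.95 M parameters", {
  student <- build_student(9)
  baseline <- build_baseline(9)
  expect_equal(param_millions(student), 0.95)
  expect_equal(param_millions(baseline), 0.95)
  # the stem swap changes only stem-sized parameter counts
  expect_equal(count_parameters(student) - count_parameters(baseline),
               1096L - 464L)
})

test_that("experts get one output node per in-group class plus 'other'", {
  head_e <- build_expert(c("Idle Period", "Mid Production"),
                         variant = "test-tiny")
  expect_equal(head_e$num_nodes, 3L)
  expect_equal(head_e$class_nodes[3], "other")
  tail_e <- build_expert(c("a", "b", "c", "d"), variant = "test-tiny")
  expect_equal(tail_e$num_nodes, 5L)
  expect_error(build_expert(character()), "at least one class")
})

test_that("model construction validates its inputs", {
  expect_error(build_student(1), ">= 2")
  expect_error(build_student(9, variant = "xxs",
                             msc = msc_spec(3L, c(1L, 1L, 1L, 1L))),
               "stem width")
  expect_error(msc_spec(branch_out = c(4, 4, 4)), "four")
})

test_that("test-tiny variant runs a forward pass and is strictly smaller than xxs", {
  tiny <- build_student(4, variant = "test-tiny", seed = 5)
  x <- withr::with_seed(2, array(rnorm(3 * 64 * 64 * 3), c(3, 64, 64, 3)))
  logits <- model_forward(tiny, x)
  expect_equal(dim(logits), c(4, 3))
  expect_true(all(is.finite(logits)))
  expect_lt(count_parameters(tiny),
            count_parameters(build_student(4, variant = "xxs")))
  cfg_t <- backbone_config("test-tiny"); cfg_x <- backbone_config("xxs")
  expect_true(all(vapply(seq_along(cfg_t$stages), function(i) {
    cfg_t$stages[[i]]$out < cfg_x$stages[[i]]$out
  }, logical(1))))
})

test_that("count_parameters counts trainable scalars exactly", {
  # a single linear head 3 -> 2 with bias: 3*2 + 2 = 8
  ctx <- tailkd:::new_ctx()
  arch <- list(fc = tailkd:::mk_head(ctx, "fc", 3L, 2L))
  m <- tailkd:::finalize_model(ctx, arch, "test", c("a", "b"), "none",
                               "none", 8L)
  expect_equal(count_parameters(m), 8L)
})

test_that("checkpoints round-trip weights and metadata", {
  m <- build_student(3, variant = "test-tiny", seed = 9)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_equal(count_parameters(m2), count_parameters(m))
  expect_identical(m2$class_nodes, m$class_nodes)
  x <- withr::with_seed(3, array(rnorm(3 * 64 * 64), c(3, 64, 64, 1)))
  expect_equal(model_forward(m2, x), model_forward(m, x))
})

test_that("tidiers summarize models", {
  m <- build_student(3, variant = "test-tiny")
  g <- glance(m)
  expect_equal(g$num_nodes, 3L)
  expect_equal(g$parameters, count_parameters(m))
  expect_true(all(c("id", "group", "n") %in% names(tidy(m))))
})
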