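test_that("bundled stage counts load into global order with correct totals", {
  man <- stage_counts()
  expect_s3_class(man, "tk_manifest")
  tot <- manifest_totals(man)
  expect_equal(tot$raw, 1999)
  expect_equal(tot$train, 1002)
  expect_equal(tot$test, 997)
  # the post-augmentation column sums to 1361 (the column sum is reported
  # as-is, not forced to a stated headline)
  expect_equal(tot$train_aug, 1361)
  # global order: descending original training count
  expect_equal(man$train, sort(man$train, decreasing = TRUE))
  expect_equal(man$class[1:2], c("Idle Period", "Mid Production"))
})

test_that("load_manifest validates structure", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("class,raw,train,test", f)
  empty <- load_manifest(f)
  expect_equal(nrow(empty), 0)
  expect_equal(manifest_totals(empty)$raw, 0)

  writeLines(c("class,raw,train,test", "a,10,5,5", "b,5,3,2", "c,20,10,10"), f)
  m <- load_manifest(f)
  expect_equal(m$class, c("c", "a", "b"))   # sorted by train desc

  writeLines(c("class,raw,train", "a,10,5"), f)
  expect_error(load_manifest(f), "missing column")
  writeLines(c("class,raw,train,test", "a,10,-5,15"), f)
  expect_error(load_manifest(f), "negative")
  writeLines(c("class,raw,train,test", "a,10,5,5", "a,10,5,5"), f)
  expect_error(load_manifest(f), "duplicate")
  writeLines(c("class,raw,train,test", "a,10,5,4"), f)
  expect_error(load_manifest(f), "train \\+ test")
})

test_that("stratified 1:1 split puts the extra image of odd classes in train", {
  sp <- stratified_split(tibble::tibble(class = c("a", "b", "c"),
                                        raw = c(59L, 608L, 1L)))
  expect_equal(sp$train, c(30L, 304L, 1L))
  expect_equal(sp$test, c(29L, 304L, 0L))
  expect_equal(sp$train + sp$test, sp$raw)
})

test_that("split assignment is a seeded permutation partition", {
  s1 <- split_indices(11, seed = 7)
  s2 <- split_indices(11, seed = 7)
  expect_identical(s1, s2)
  expect_length(s1$train, 6)
  expect_length(s1$test, 5)
  expect_setequal(c(s1$train, s1$test), 1:11)
  expect_false(identical(split_indices(11, seed = 8), s1))
  expect_identical(split_indices(0, 1), list(train = integer(),
                                             test = integer()))
})

test_that("grouping thresholds reproduce the reference head/balance/tail partition", {
  g <- assign_groups(stage_counts())
  gl <- group_classes(g)
  expect_equal(gl$Head, c("Idle Period", "Mid Production"))
  expect_equal(gl$Balance, c("Late Production", "Seedling Pulling", "Planting"))
  expect_equal(gl$Tail, c("Substrate Placement", "Hole Opening",
                          "Substrate Soaking", "Early Production"))
  # concatenating group lists reproduces the global class order
  expect_equal(unlist(gl, use.names = FALSE), stage_counts()$class)
})

test_that("grouping edge cases and validation", {
  man <- as_manifest(tibble::tibble(class = c("a", "b"), raw = c(600, 600),
                                    train = c(300, 300), test = c(300, 300)))
  g <- assign_groups(man, head_min = 200, balance_min = 50)
  expect_true(all(g$group == "Head"))
  expect_equal(lengths(group_classes(g))[["Balance"]], 0L)

  single <- as_manifest(tibble::tibble(class = "a", raw = 20, train = 10,
                                       test = 10))
  expect_equal(as.character(assign_groups(single)$group), "Tail")

  expect_error(assign_groups(man[0, ]), "empty")
  expect_error(assign_groups(man, head_min = 50, balance_min = 50),
               "head_min > balance_min")
})

test_that("augmentation plan reproduces the reference post-augmentation counts", {
  man <- stage_counts()
  plan <- plan_augmentation(man)
  expect_equal(plan$post_count, man$train_aug)
  # the five augmented classes get multipliers ceiling(90 / n) and m - 1
  # distinct transforms from the seven-transform list
  aug <- plan[plan$multiplier > 1, ]
  expect_equal(aug$multiplier, c(2L, 3L, 4L, 6L, 8L))
  expect_equal(sort(aug$post_count), sort(c(114L, 90L, 104L, 96L, 96L)))
  for (i in seq_len(nrow(plan))) {
    tf <- plan$transforms[[i]]
    expect_length(tf, plan$multiplier[i] - 1L)
    expect_true(all(tf %in% transform_names()))
    expect_false(anyDuplicated(tf) > 0)
  }
  # multiplier capped at 8 (original + at most 7 transforms)
  tiny <- as_manifest(tibble::tibble(class = "a", raw = 4, train = 2,
                                     test = 2))
  expect_equal(plan_augmentation(tiny)$multiplier, 8L)
  # above-threshold class untouched
  big <- as_manifest(tibble::tibble(class = "a", raw = 300, train = 150,
                                    test = 150))
  p <- plan_augmentation(big)
  expect_equal(p$multiplier, 1L)
  expect_equal(p$post_count, 150L)
})
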