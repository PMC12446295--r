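test_that("confusion matrix counts exactly and validates labels", {
  cm <- confusion_matrix(c(1, 1, 2, 2), c(1, 2, 2, 2), c("a", "b"))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 2L), 2, 2,
                                   dimnames = list(true = c("a", "b"),
                                                   predicted = c("a", "b"))),
               ignore_attr = "class")
  expect_equal(rowSums(cm), c(a = 2, b = 2))
  perfect <- confusion_matrix(1:3, 1:3, 3)
  expect_equal(unname(diag(perfect)), rep(1L, 3))
  expect_equal(sum(perfect) - sum(diag(perfect)), 0)
  expect_error(confusion_matrix(c(1, 4), c(1, 1), 3), "outside")
})

test_that("micro accuracy is pooled trace over total", {
  cm <- cm_from_recalls(c(100, 50), c(2, 2), c("a", "b"))
  expect_equal(micro_accuracy(cm), 75)
  expect_equal(micro_accuracy(confusion_matrix(1:3, 1:3, 3)), 100)
  expect_error(micro_accuracy(matrix(0L, 2, 2)), "empty")
})

test_that("macro metrics are unweighted means of per-class values", {
  cm <- matrix(c(1L, 0L, 1L, 2L), 2, 2,
               dimnames = list(true = c("a", "b"), predicted = c("a", "b")))
  rep <- metrics_report(cm)
  expect_equal(rep$per_class$recall, c(50, 100))
  expect_equal(rep$macro$recall, 75)
  diagm <- confusion_matrix(1:4, 1:4, 4)
  repd <- metrics_report(diagm)
  expect_equal(repd$macro$precision, 100)
  expect_equal(repd$macro$f1, 100)
  # never-predicted class is flagged with precision 0
  cm0 <- confusion_matrix(c(1, 2), c(1, 1), 2)
  r0 <- metrics_report(cm0)
  expect_true(r0$per_class$never_predicted[2])
  expect_equal(r0$per_class$precision[2], 0)
})

test_that("group accuracy pools within groups; single group equals overall", {
  man <- as_manifest(tibble::tibble(class = c("a", "b"), raw = c(600, 500),
                                    train = c(300, 250), test = c(300, 250)))
  asg <- assign_groups(man, head_min = 200, balance_min = 50)
  cm <- cm_from_recalls(c(90, 70), c(300, 250), c("a", "b"))
  gr <- group_accuracy(cm, asg)
  expect_equal(nrow(gr), 1)
  expect_equal(gr$accuracy, micro_accuracy(cm))
  asg$class[2] <- "zzz"
  expect_error(group_accuracy(cm, asg), "missing from assignment")
})

test_that("group gap is max minus min and needs two groups", {
  expect_equal(group_gap(c(95.32, 91.17, 79.27)), 16.05)
  expect_equal(group_gap(c(97.32, 94.32, 93.83)), 3.49)
  expect_equal(group_gap(c(80, 80, 80)), 0)
  expect_error(group_gap(c(50)), "two groups")
  # tautology: gap + min = max
  acc <- c(97.32, 94.32, 93.83)
  expect_equal(group_gap(acc) + min(acc), max(acc))
})

test_that("stratified k-fold partitions evenly, deterministically", {
  y <- rep(1:3, c(10, 15, 5))
  folds <- stratified_kfold(y, k = 5, seed = 4)
  vals <- lapply(folds, `[[`, "val")
  expect_setequal(unlist(vals), seq_along(y))
  expect_equal(sum(lengths(vals)), length(y))
  expect_equal(anyDuplicated(unlist(vals)), 0)
  # class of 10 -> exactly 2 per validation fold; train/val disjoint
  for (f in folds) {
    expect_equal(sum(y[f$val] == 1), 2)
    expect_length(intersect(f$train, f$val), 0)
    expect_setequal(c(f$train, f$val), seq_along(y))
  }
  expect_identical(folds, stratified_kfold(y, k = 5, seed = 4))
  expect_error(stratified_kfold(rep(1:2, c(10, 3)), k = 5), "fewer than k")
})

test_that("cv_stats uses the population standard deviation", {
  s <- cv_stats(c(96.03, 95.88, 95.71, 97.24, 95.44))
  expect_equal(s$mean, 96.06)
  expect_equal(s$sd, 0.62)
  expect_equal(cv_stats(rep(50, 4))$sd, 0)
  expect_error(cv_stats(numeric()), "no fold values")
})

test_that("grad-cam combination follows the channel-weighting formula", {
  withr::with_seed(14, {
    act <- array(runif(4 * 3 * 3), c(4, 3, 3))
    # uniform positive gradients -> map proportional to channel-mean activation
    grad1 <- array(1, c(4, 3, 3))
    m <- tailkd:::gradcam_combine(act, grad1)
    expect_equal(m, matrix(colSums(matrix(act, 4)), 3, 3), tolerance = 1e-12)
    # zero gradients -> all-zero map
    expect_equal(tailkd:::gradcam_combine(act, array(0, c(4, 3, 3))),
                 matrix(0, 3, 3))
  })
})

test_that("grad-cam heatmaps are normalized maps at input resolution", {
  m <- build_student(3, variant = "test-tiny", seed = 6)
  x <- withr::with_seed(15, array(rnorm(3 * 64 * 64), c(3, 64, 64)))
  hm <- gradcam_heatmap(m, x, target_class = 2, layer = "stage4")
  expect_equal(dim(hm), c(64, 64))
  expect_true(all(hm >= 0 & hm <= 1))
  expect_error(gradcam_heatmap(m, x, 1, layer = "nope"), "available")
})
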