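make_assignment <- function() {
  man <- as_manifest(tibble::tibble(
    class = c("h1", "h2", "b1", "b2", "b3", "t1", "t2", "t3", "t4"),
    raw = c(600, 580, 260, 250, 110, 58, 50, 30, 22),
    train = c(300, 290, 130, 125, 55, 29, 25, 15, 11),
    test = c(300, 290, 130, 125, 55, 29, 25, 15, 11)))
  assign_groups(man, head_min = 200, balance_min = 50)
}

test_that("tempered softmax matches its closed form and limits", {
  expect_equal(tempered_softmax(c(0, 0), 1), c(0.5, 0.5))
  expect_equal(tempered_softmax(c(1, 0), 1),
               c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-7)
  expect_equal(unname(tempered_softmax(c(1, 0), 1)[1]), 0.7311,
               tolerance = 1e-4)
  expect_equal(tempered_softmax(c(1, 0), 1e6), c(0.5, 0.5), tolerance = 1e-5)
  expect_error(tempered_softmax(c(1, 0), 0), "temperature")
  zm <- matrix(rnorm(12), 4, 3)
  expect_equal(colSums(tempered_softmax(zm, 3)), rep(1, 3))
})

test_that("softmax entropy is non-decreasing in temperature", {
  withr::with_seed(10, {
    for (rep in 1:20) {
      z <- rnorm(sample(2:9, 1), sd = 3)
      ent <- vapply(c(0.5, 1, 2, 4, 8, 16),
                    function(Tt) shannon_entropy(tempered_softmax(z, Tt)),
                    numeric(1))
      expect_true(all(diff(ent) >= -1e-10))
    }
  })
})

test_that("splicing drops 'other' nodes and restores global class order", {
  asg <- make_assignment()
  outs <- list(Head = c(1, 2, 9), Balance = c(3, 4, 5, 9),
               Tail = c(6, 7, 8, 9, 9))
  z <- splice_expert_logits(outs, asg)
  expect_length(z, 9)
  expect_equal(unname(z), c(1, 2, 3, 4, 5, 6, 7, 8, 9))
  expect_equal(names(z), asg$class)   # bijection onto global order
  # matrix form
  zm <- splice_expert_logits(lapply(outs, function(v) cbind(v, v + 1)), asg)
  expect_equal(dim(zm), c(9, 2))
  # single group covering all classes = identity minus "other"
  man1 <- as_manifest(tibble::tibble(class = c("a", "b"), raw = c(600, 500),
                                     train = c(300, 250), test = c(300, 250)))
  asg1 <- assign_groups(man1, head_min = 200, balance_min = 50)
  expect_equal(unname(splice_expert_logits(list(Head = c(5, 7, 0)), asg1)),
               c(5, 7))
  # node-count mismatch and missing group
  expect_error(splice_expert_logits(list(Head = c(1, 2), Balance = outs[[2]],
                                         Tail = outs[[3]]), asg),
               "expected 3")
  expect_error(splice_expert_logits(outs[c("Head", "Tail")], asg), "missing")
})

test_that("ensemble prediction uses softmax argmax with lowest-index ties", {
  asg <- make_assignment()
  outs <- list(Head = c(0, 0, 0), Balance = c(0, 0, 9, 0),
               Tail = c(0, 0, 0, 0, 0))
  expect_equal(unname(ensemble_predict(outs, asg)), 5L)  # dominant block wins
  flat <- list(Head = c(0, 0, 0), Balance = c(0, 0, 0, 0),
               Tail = c(0, 0, 0, 0, 0))
  expect_equal(unname(ensemble_predict(flat, asg)), 1L)  # tie -> lowest index
  p <- tempered_softmax(splice_expert_logits(outs, asg), 1)
  expect_equal(sum(p), 1)
})

test_that("loss values match hand evaluations", {
  # as-printed orientation at p=(.5,.5), q=softmax(1,0)
  q <- tempered_softmax(c(1, 0), 1)
  cfg_ap <- distill_config(orientation = "as-printed", temperature = 1)
  expect_equal(soft_loss(c(0.5, 0.5), q, cfg_ap),
               -0.5 * (log(q[1]) + log(q[2])), tolerance = 1e-12)
  expect_equal(soft_loss(c(0.5, 0.5), q, cfg_ap), 0.8133, tolerance = 1e-4)
  # matching degenerate distributions: loss -> entropy -> 0
  sharp <- c(1 - 1e-9, 1e-9)
  expect_lt(soft_loss(sharp, sharp), 1e-6)
  # Gibbs: cross-entropy >= entropy of the outer distribution
  withr::with_seed(11, for (rep in 1:10) {
    p <- tempered_softmax(rnorm(5), 1)
    q2 <- tempered_softmax(rnorm(5), 1)
    expect_gte(soft_loss(p, q2, cfg_ap) + 1e-12, shannon_entropy(p))
    # KL(q||p) = -sum q log p - H(q) >= 0
    cfg_std <- distill_config(orientation = "standard", temperature = 1)
    expect_gte(soft_loss(p, q2, cfg_std) - shannon_entropy(q2), -1e-12)
  })
  # hard loss closed forms
  expect_equal(hard_loss(c(0, 0), 1L), log(2), tolerance = 1e-12)
  expect_lt(hard_loss(c(50, 0), 1L), 1e-9)
  # focal with gamma = 0 reduces to cross-entropy
  v <- c(0.3, -1.2, 0.8)
  expect_equal(hard_loss(v, 2L, distill_config(hard_loss = "focal",
                                               gamma = 0)),
               hard_loss(v, 2L), tolerance = 1e-12)
  expect_error(hard_loss(c(0, 0), 3L), "out of range")
})

test_that("combined loss is the exact affine combination", {
  expect_equal(combined_loss(0.8, 0.6, 0.5), 0.7)
  expect_equal(combined_loss(0.8, 0.6, 1), 0.8)
  expect_equal(combined_loss(0.8, 0.6, 0), 0.6)
  expect_error(combined_loss(1, 1, 1.5), "alpha")
  # gradient is affine in alpha as well
  withr::with_seed(12, {
    v <- rnorm(6); q <- tempered_softmax(rnorm(6), 4)
    for (a in c(0, 0.3, 1)) {
      cfg <- distill_config(alpha = a)
      expect_equal(distill_grad(v, q, 2L, cfg),
                   a * soft_loss_grad(v, q, cfg) +
                     (1 - a) * hard_loss_grad(v, 2L, cfg), tolerance = 1e-14)
    }
  })
})

test_that("analytic loss gradients match central finite differences", {
  withr::with_seed(13, {
    cfgs <- list(
      distill_config(),
      distill_config(orientation = "as-printed"),
      distill_config(temperature = 2, t2_scale = TRUE),
      distill_config(hard_loss = "focal", gamma = 2),
      distill_config(alpha = 0.25, temperature = 7)
    )
    for (cfg in cfgs) {
      v <- rnorm(7); q <- tempered_softmax(rnorm(7, sd = 2), cfg$temperature)
      cls <- sample(7, 1)
      lsoft <- function(vv) {
        soft_loss(tempered_softmax(vv, cfg$temperature), q, cfg)
      }
      lhard <- function(vv) hard_loss(vv, cls, cfg)
      lk <- function(vv) combined_loss(lsoft(vv), lhard(vv), cfg$alpha)
      gs <- soft_loss_grad(v, q, cfg)
      gh <- hard_loss_grad(v, cls, cfg)
      gk <- distill_grad(v, q, cls, cfg)
      for (i in seq_along(v)) {
        expect_lt(fd_rel_error(lsoft, v, gs, i), 1e-4)
        expect_lt(fd_rel_error(lhard, v, gh, i), 1e-4)
        expect_lt(fd_rel_error(lk, v, gk, i), 1e-4)
      }
    }
  })
})

test_that("distillation with alpha = 0 equals plain training, experts stay frozen", {
  ds <- make_synth_dataset(c(a = 8L, b = 6L, c = 4L), side = 32L, seed = 23)
  man <- as_manifest(tibble::tibble(class = c("a", "b", "c"),
                                    raw = c(16, 12, 8), train = c(8, 6, 4),
                                    test = c(8, 6, 4)))
  asg <- assign_groups(man, head_min = 8, balance_min = 5)
  experts <- list(
    Head = train_expert("a", ds, train_config(epochs = 1, batch_size = 8,
                                              seed = 2),
                        variant = "test-tiny", seed = 41),
    Balance = train_expert("b", ds, train_config(epochs = 1, batch_size = 8,
                                                 seed = 3),
                           variant = "test-tiny", seed = 42),
    Tail = train_expert("c", ds, train_config(epochs = 1, batch_size = 8,
                                              seed = 4),
                        variant = "test-tiny", seed = 43))
  before <- lapply(experts, function(e) as.list(e$params))

  s1 <- build_student(3, variant = "test-tiny", class_names = ds$class_names,
                      seed = 77)
  distill_student(s1, experts, ds, asg,
                  train_config(epochs = 2, batch_size = 8, seed = 5),
                  distill_config(alpha = 0))
  s2 <- build_student(3, variant = "test-tiny", class_names = ds$class_names,
                      seed = 77)
  train_model(s2, ds, train_config(epochs = 2, batch_size = 8, seed = 5))
  expect_equal(utils::tail(s1$log$loss, 1), utils::tail(s2$log$loss, 1),
               tolerance = 1e-12)
  x <- ds$x[, , , 1:2, drop = FALSE]
  expect_equal(model_forward(s1, x), model_forward(s2, x), tolerance = 1e-10)

  # frozen teachers: parameters unchanged by distillation
  for (g in names(experts)) {
    for (id in ls(experts[[g]]$params)) {
      expect_identical(experts[[g]]$params[[id]], before[[g]][[id]])
    }
  }
})

test_that("teacher logits splice to the student's output length", {
  ds <- make_synth_dataset(c(a = 4L, b = 4L, c = 4L), side = 32L, seed = 3)
  man <- as_manifest(tibble::tibble(class = c("a", "b", "c"),
                                    raw = c(8, 8, 8), train = c(4, 4, 4),
                                    test = c(4, 4, 4)))
  asg <- assign_groups(man, head_min = 4, balance_min = 1)
  experts <- list(Head = build_expert(c("a", "b", "c"),
                                      variant = "test-tiny", seed = 1))
  zt <- teacher_logits(experts, ds, asg)
  expect_equal(dim(zt), c(3, 12))
  expect_equal(rownames(zt), c("a", "b", "c"))
})
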