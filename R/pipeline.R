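# End-to-end pipeline: synthesize -> split -> augment -> group ->
# train experts -> distill student -> evaluate, with per-stage caching
# keyed by a config hash.

#' Read a pipeline run configuration
#'
#' YAML with sections `data`, `groups`, `train`, `distill`, `eval` (plus
#' optional `augment`), a global `seed` and an `out_dir`. Every stochastic
#' component derives its seed from the global one.
#'
#' @param path YAML file path.
#' @return The validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  need <- c("data", "groups", "train", "distill", "eval")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    rlang::abort(sprintf("config is missing section(s): %s",
                         paste(missing, collapse = ", ")))
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "tailkd-run"
  cfg
}

pipeline_paths <- function(out_dir) {
  list(root = out_dir,
       data = file.path(out_dir, "data"),
       train = file.path(out_dir, "split", "train"),
       test = file.path(out_dir, "split", "test"),
       models = file.path(out_dir, "models"),
       reports = file.path(out_dir, "reports"))
}

stage_done <- function(marker, hash) {
  file.exists(marker) && identical(readLines(marker, warn = FALSE)[1], hash)
}

mark_stage <- function(marker, hash) {
  writeLines(hash, marker)
}

#' Run the full pipeline
#'
#' Executes synthesize (when `data$source` is `"synthetic"`) -> stratified
#' split -> small-class augmentation -> grouping -> expert training ->
#' student distillation -> evaluation of student, plain baseline and
#' expert ensemble. Stages are cached: a stage whose inputs (config hash)
#' are unchanged is skipped on rerun, and two runs with the same config
#' and seed produce byte-identical metrics JSON.
#'
#' @param config A config list or YAML path (see [read_run_config()]).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the manifest, group assignment, models
#'   and the three evaluation reports.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  cfg <- if (is.character(config)) read_run_config(config)
         else validate_run_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  hash <- rlang::hash(cfg[c("data", "augment", "groups", "train", "distill",
                            "seed")])
  p <- pipeline_paths(cfg$out_dir)
  for (d in p) dir.create(d, showWarnings = FALSE, recursive = TRUE)
  seeds <- seed_stream(cfg$seed, 16L)
  side <- as.integer(cfg$data$side %||% 64L)

  # -- data ------------------------------------------------------------------
  marker <- file.path(p$data, ".stage")
  if (!stage_done(marker, hash)) {
    if (identical(cfg$data$source %||% "synthetic", "synthetic")) {
      say("synthesizing dataset")
      sc <- synthetic_config(
        counts = synthetic_profile(as.integer(cfg$data$divisor %||% 8L)),
        side = side, noise_sd = cfg$data$noise_sd %||% 8, seed = seeds[1])
      generate_dataset(sc, p$data, overwrite = TRUE)
    } else {
      rlang::abort("only data source 'synthetic' is built in; point `data$dir` stages at an existing tree instead")
    }
    mark_stage(marker, hash)
  }
  manifest <- load_manifest(file.path(p$data, "manifest.csv"))

  # -- split + augment -------------------------------------------------------
  marker <- file.path(dirname(p$train), ".stage")
  if (!stage_done(marker, hash)) {
    say("splitting 1:1 and augmenting small classes")
    unlink(c(p$train, p$test), recursive = TRUE)
    for (i in seq_len(nrow(manifest))) {
      cl <- manifest$class[i]
      files <- list.files(file.path(p$data, cl), pattern = "\\.png$",
                          full.names = TRUE)
      sp <- split_indices(length(files), seeds[2] + i)
      for (half in c("train", "test")) {
        dest <- file.path(p[[half]], cl)
        dir.create(dest, showWarnings = FALSE, recursive = TRUE)
        file.copy(files[sp[[half]]], dest)
      }
    }
    aug <- cfg$augment %||% list()
    if (isTRUE(aug$enabled %||% TRUE)) {
      plan <- plan_augmentation(
        manifest,
        small_class_threshold = aug$small_class_threshold %||% 13L,
        floor_target = aug$floor_target %||% 12L,
        seed = seeds[3])
      for (i in seq_len(nrow(plan))) {
        if (plan$multiplier[i] > 1) {
          augment_class_folder(file.path(p$train, plan$class[i]),
                               plan$multiplier[i], plan$transforms[[i]],
                               seed = seeds[3] + i)
        }
      }
    }
    mark_stage(marker, hash)
  }
  train_ds <- dataset_from_dir(p$train, manifest$class, side)
  test_ds <- dataset_from_dir(p$test, manifest$class, side)

  # -- grouping --------------------------------------------------------------
  assignment <- assign_groups(manifest,
                              head_min = cfg$groups$head_min %||% 200L,
                              balance_min = cfg$groups$balance_min %||% 50L)
  readr::write_csv(tibble::as_tibble(assignment),
                   file.path(p$reports, "groups.csv"))
  gl <- group_classes(assignment)
  gl <- gl[lengths(gl) > 0]

  tcfg <- train_config(
    epochs = cfg$train$epochs %||% 20L,
    batch_size = cfg$train$batch_size %||% 32L,
    lr_backbone = cfg$train$lr_backbone %||% 0.001,
    lr_head = cfg$train$lr_head %||% 0.01,
    seed = seeds[4], pretrained = cfg$train$pretrained)
  expert_variant <- cfg$train$expert_variant %||% "test-tiny"
  student_variant <- cfg$train$student_variant %||% "test-tiny"

  # -- experts ---------------------------------------------------------------
  experts <- list()
  for (g in names(gl)) {
    ck <- file.path(p$models, paste0("expert-", tolower(g), ".rds"))
    if (stage_done(paste0(ck, ".stage"), hash) && file.exists(ck)) {
      experts[[g]] <- load_checkpoint(ck)
    } else {
      say("training %s expert (%d classes)", g, length(gl[[g]]))
      ecfg <- tcfg; ecfg$seed <- seeds[5] + match(g, names(gl))
      experts[[g]] <- train_expert(gl[[g]], train_ds, ecfg,
                                   variant = expert_variant,
                                   seed = seeds[6] + match(g, names(gl)))
      save_checkpoint(experts[[g]], ck)
      mark_stage(paste0(ck, ".stage"), hash)
    }
  }

  # -- student (distilled) and baseline --------------------------------------
  dcfg <- distill_config(
    temperature = cfg$distill$temperature %||% 4,
    alpha = cfg$distill$alpha %||% 0.5,
    orientation = cfg$distill$orientation %||% "standard",
    hard_loss = cfg$distill$hard_loss %||% "cross-entropy",
    gamma = cfg$distill$gamma %||% 2)
  K <- nrow(manifest)
  ck_student <- file.path(p$models, "student.rds")
  if (stage_done(paste0(ck_student, ".stage"), hash) &&
      file.exists(ck_student)) {
    student <- load_checkpoint(ck_student)
  } else {
    say("distilling student")
    scfg <- tcfg; scfg$seed <- seeds[7]
    student <- build_student(K, variant = student_variant,
                             class_names = manifest$class, seed = seeds[8])
    distill_student(student, experts, train_ds, assignment, scfg, dcfg)
    save_checkpoint(student, ck_student)
    mark_stage(paste0(ck_student, ".stage"), hash)
  }
  ck_base <- file.path(p$models, "baseline.rds")
  if (stage_done(paste0(ck_base, ".stage"), hash) && file.exists(ck_base)) {
    baseline <- load_checkpoint(ck_base)
  } else {
    say("training non-distilled baseline")
    bcfg <- tcfg; bcfg$seed <- seeds[7]   # identically-trained comparison
    baseline <- build_student(K, variant = student_variant,
                              class_names = manifest$class, seed = seeds[8])
    train_model(baseline, train_ds, bcfg)
    save_checkpoint(baseline, ck_base)
    mark_stage(paste0(ck_base, ".stage"), hash)
  }

  # -- evaluation ------------------------------------------------------------
  say("evaluating")
  bs <- as.integer(cfg$eval$batch_size %||% 64L)
  reports <- list(
    student = evaluate_model(student, test_ds, bs),
    baseline = evaluate_model(baseline, test_ds, bs)
  )
  zt <- teacher_logits(experts, test_ds, assignment, bs)
  pred <- max.col(t(zt), ties.method = "first")
  cm <- confusion_matrix(test_ds$y, pred, test_ds$class_names)
  reports$ensemble <- structure(
    list(cm = cm, metrics = metrics_report(cm), pred = pred),
    class = "tk_eval")
  for (nm in names(reports)) {
    write_eval_report(reports[[nm]], assignment,
                      file.path(p$reports, paste0(nm, ".json")),
                      config_hash = hash, seed = cfg$seed)
    utils::write.csv(unclass(reports[[nm]]$cm),
                     file.path(p$reports, paste0(nm, "-confusion.csv")))
  }
  invisible(list(manifest = manifest, assignment = assignment,
                 experts = experts, student = student, baseline = baseline,
                 reports = reports))
}

write_eval_report <- function(ev, assignment, path, config_hash, seed) {
  grp <- group_accuracy(ev$cm, assignment)
  out <- list(
    config_hash = config_hash,
    seed = seed,
    n = ev$metrics$n,
    accuracy = round_half_up(ev$metrics$macro$accuracy, 2),
    macro_precision = round_half_up(ev$metrics$macro$precision, 2),
    macro_recall = round_half_up(ev$metrics$macro$recall, 2),
    macro_f1 = round_half_up(ev$metrics$macro$f1, 2),
    per_class = as.list(stats::setNames(
      round_half_up(ev$metrics$per_class$recall, 2),
      ev$metrics$per_class$class)),
    group_accuracy = as.list(stats::setNames(
      round_half_up(grp$accuracy, 2), grp$group)),
    group_gap = group_gap(grp)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Stratified cross-validation of a trainer
#'
#' Splits `data` with [stratified_kfold()], trains a fresh model per fold
#' via `trainer(train_ds, fold_seed)` and evaluates it on the fold's
#' validation split.
#'
#' @param data A `tk_dataset`.
#' @param trainer Function `(train_ds, seed) -> tk_model`.
#' @param k Number of folds.
#' @param seed Seed for fold assignment and per-fold training.
#' @return List with per-fold metrics tibble `folds` and `stats` (mean and
#'   population sd per metric).
#' @export
cross_validate <- function(data, trainer, k = 5L, seed = 1L) {
  folds <- stratified_kfold(data$y, k, seed)
  seeds <- seed_stream(seed + 1L, k)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    model <- trainer(dataset_subset(data, folds[[i]]$train), seeds[i])
    ev <- evaluate_model(model, dataset_subset(data, folds[[i]]$val))
    rows[[i]] <- tibble::tibble(
      fold = paste0("K", i),
      accuracy = ev$metrics$macro$accuracy,
      precision = ev$metrics$macro$precision,
      recall = ev$metrics$macro$recall,
      f1 = ev$metrics$macro$f1)
  }
  folds_tbl <- dplyr::bind_rows(rows)
  stats <- dplyr::bind_rows(lapply(c("accuracy", "precision", "recall", "f1"),
    function(mname) {
      s <- cv_stats(folds_tbl[[mname]])
      tibble::tibble(metric = mname, mean = s$mean, sd = s$sd)
    }))
  list(folds = folds_tbl, stats = stats)
}
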