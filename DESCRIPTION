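Package: tailkd
Title: Multi-Expert Knowledge Distillation for Long-Tailed Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Sub-group guided multi-expert knowledge distillation for
    long-tailed image classification, built around the cultivation-stage
    recognition problem in greenhouse tomato production. Classes are split
    into head/balance/tail groups by training-sample count, one open-set
    expert (with a trailing "other" node) is trained per group, expert
    logits are spliced back into a full class vector, and a lightweight
    multi-scale-stem MobileViT student is trained against the ensemble's
    temperature-softened soft labels. Includes a long-tailed synthetic
    image generator, the seven-transform augmentation pipeline, a compact
    CPU neural-network engine with exact backpropagation, the full metrics
    engine (micro/macro precision-recall-F1, per-group accuracy and group
    gap, stratified cross-validation statistics, Grad-CAM), and an
    end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
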