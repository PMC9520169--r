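Package: opensetr
Title: Open-Set Recognition with Outlier Exposure for Plant Disease Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training and evaluating open-set recognition models that
    classify known plant-disease categories while flagging unknown ones. Implements
    two complementary detectors sharing one trainable backbone: a two-head network
    whose inter-head L1 discrepancy on a sample is its outlier evidence (trained
    with a margin hinge on exposed outliers, then improved by pseudo-labeling,
    FixMatch consistency and supervised contrastive regularization), and a
    disassembled semi-supervised OpenMatch with per-class one-vs-all heads,
    entropy minimization and soft open-set consistency regularization. Includes a
    deterministic synthetic image generator emulating a multi-class disease
    dataset with three outlier families, weak/strong augmentation policies,
    evaluation metrics (accuracy over K+1 outcomes, AUROC, per-class
    precision/recall), and an ablation harness over outlier-exposure
    compositions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
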