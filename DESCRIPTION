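Package: mtorresponse
Title: Integrative Machine-Learning Biomarker for mTOR Inhibitor Response
    in ER+ Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and evaluates an integrative transcriptomic biomarker of
    clinical everolimus (mTOR inhibitor) response in estrogen-receptor-positive
    breast cancer. An in vitro treatment-response signature is derived from
    cell-line expression profiles by correlation-based gene selection, singular
    value decomposition metagenes and Bayesian probit regression fitted with an
    Albert-Chib Gibbs sampler. Clinical features are selected with the Fast
    Correlation-Based Filter (symmetrical uncertainty with predominance-based
    redundancy removal), fused with the in vitro signature, and used to train
    mtry-tuned random forests inside a leakage-free leave-one-out
    cross-validation. Includes external-cohort scoring with one-way ANOVA and
    Tukey HSD group comparison, and seeded synthetic-data generators for
    cell-line and patient cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
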