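Package: screg
Title: Supervised Contrastive Regression for High-Dimensional Tabular
    Tractometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts continuous outcomes (e.g., neurocognitive component
    scores) from high-dimensional tabular features such as fiber-cluster
    tractometry measures, using supervised contrastive representation
    learning for regression. Positive and negative sample pairs are
    determined from the absolute difference between continuous labels,
    random feature corruption provides tabular data augmentation, and a
    two-phase procedure (contrastive pretraining of an encoder, then
    frozen-encoder fine-tuning of a regression head with mean squared
    error) yields the predictor. Includes per-measure ensembling by
    prediction averaging, a grouped permutation feature-importance
    algorithm for high-dimensional inputs with per-category aggregation,
    a repeated-split Pearson-correlation evaluation protocol with paired
    tests, and a synthetic tractometry data generator with planted sparse
    linear signal and a closed-form noise ceiling.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
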