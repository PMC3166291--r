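Package: tsmut
Title: Structure-Informed Prediction of Temperature-Sensitive Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts candidate temperature-sensitive (ts) point mutations in
    buried protein sites from ensembles of structure-relaxation scores.
    Per-mutation score ensembles are compared to the wild-type ensemble with a
    distribution-free quartile-to-percentile mapping, combined with
    sequence-derived features (amino-acid category change, PSI-BLAST PSSM
    log-odds and frequencies) and structure features (solvent accessibility,
    secondary structure), pruned for redundancy, and classified with support
    vector machines (linear and RBF kernels). Includes a nested
    cross-validation harness with hyperparameter grid search, ranking of
    candidate substitutions by calibrated confidence, and a synthetic-data
    generator that emulates every upstream input so the full pipeline can be
    exercised without external structure-modelling runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
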