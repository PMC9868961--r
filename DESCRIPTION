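Package: crisprcleavr
Title: Benchmarking Machine-Learning Classifiers for CRISPR-Cas9 Cleavage
    Sites in Plant Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies candidate CRISPR-Cas9 cleavage sites in plant
    genomes as on-target or off-target from sequence-derived features.
    Provides semi-global alignment of a guide RNA to a candidate
    protospacer with RNA/DNA bulge support and mismatch typing (wobble,
    transversion, purine-purine, pyrimidine-pyrimidine), a 30-feature
    registry covering alignment, nucleotide-content and PAM-site blocks
    (including nearest-neighbor DNA enthalpy over an extended window), a
    synthetic labeled-dataset generator emulating curated crop data, an
    eleven-model suite (six multilayer perceptrons, four support vector
    machines, one random forest) trained with a 70/30 holdout and 5-fold
    cross-validation, an eight-metric evaluation suite with ROC/AUC, and
    TOPSIS multi-criteria ranking of the fitted models.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
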