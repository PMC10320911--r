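Package: iecscore
Title: Theory-Based Interaction Energy Component Scoring for Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Machine-learning scoring functions for structure-based virtual
    screening built from physicochemically grouped protein-ligand interaction
    energy components. Computes Vina/Smina-style pair-potential terms and an
    NNScore-2-style atom-type contact and electrostatics block from docked
    3-D complexes, organises energy terms from classical scoring functions
    into a twelve-group interaction taxonomy, enumerates theory-based feature
    combinations (formula-based and tree-importance-based), and trains tuned
    SVM, random-forest and gradient-boosted-tree classifiers evaluated with
    screening metrics (F1, ROC AUC, enrichment factors). Includes a synthetic
    complex and screening-set generator with planted, exactly countable
    interactions so every layer is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    bio3d,
    ChemmineR,
    igraph,
    e1071,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    randomForest,
    withr
Config/testthat/edition: 3
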