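Package: qnasom
Title: Site-of-Metabolism Prediction from QNA Atomic Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Atom-level prediction of cytochrome P450 sites of metabolism (SOM)
    from Quantitative Neighborhoods of Atoms (QNA) descriptors. Reads and writes
    SOM-annotated SDF (MDL V2000) files, computes per-atom P and Q descriptors
    from the hydrogen-suppressed connectivity matrix and tabulated atomic
    ionization potentials and electron affinities, builds per-atom classification
    datasets grouped by metabolic reaction type and CYP isoform, balances the
    rare SOM class with SMOTE oversampling, fits naive Bayes, random forest,
    RBF-network and multilayer-perceptron classifiers, and evaluates them with
    sensitivity, specificity, balanced accuracy, ROC AUC, repeated 2:1
    molecule-level splits, leave-one-molecule-out cross-validation and Top-k
    hit rates. A synthetic-molecule generator with a known descriptor-space
    labelling rule supports end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
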