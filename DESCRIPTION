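Package: periyield
Title: Two-Stage Prediction of Soluble Periplasmic Protein Expression Yield
Version: 0.1.0
Authors@R: person("periyield", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Predicts the soluble expression yield of a signal-peptide /
    target-protein fusion in the Escherichia coli periplasm from the amino
    acid sequence alone. A first-stage multi-class support vector classifier
    (RBF kernel, one-against-one with pairwise-coupled class probabilities)
    assigns the sequence to a high, medium or low expression class; a
    class-specific epsilon support vector regression model then predicts the
    real-valued yield in mg/l. Includes the complete feature-engineering
    scheme (7,903 sequence-derived features: 122 base features, 7,381
    pairwise interaction products and 400 dipeptide occurrences), Z-score
    standardization, correlation-based feature selection with forward
    search, repeated stratified k-fold and leave-one-out cross validation,
    macro-averaged multi-class metrics, leave-one-feature-out ablation, a
    synthetic labelled-dataset generator with planted sequence signals, and
    a command-line interface, so models can be retrained from any labelled
    dataset of sequences and yields.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    quadprog,
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
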