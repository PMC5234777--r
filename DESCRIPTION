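Package: synergyscreen
Title: Predicting Synergistic and Genotype-Selective Drug Combinations from
    Single-Agent Dose-Response Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for combinatorial drug screens in genotyped
    cell-line panels. Fits the median-effect (mass-action) model to
    single-agent dose-response data, derives GI50-type potency summaries,
    scores drug combinations with the Chou-Talalay combination index (and
    Bliss excess), converts scores into rule-based synergy, effectiveness and
    genotype-selectivity labels, builds per-cell-line mean/difference feature
    vectors for drug pairs, and trains and evaluates random-forest classifiers
    (cross-validation, robustness to training-set subsampling, sham
    self-combination controls, Gini feature importance). Includes a synthetic
    screen simulator with planted Loewe-type interactions so every stage is
    testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
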