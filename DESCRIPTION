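Package: fmosom
Title: Atom-Level Site-of-Metabolism Prediction for Flavin-Containing
    Monooxygenase Substrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts which nitrogen and sulfur atoms of a small molecule are
    likely sites of metabolism (SOMs) for flavin-containing monooxygenase (FMO)
    enzymes.  Each candidate atom is described by five quantum-mechanics
    features (Mulliken charge, condensed Fukui indices f+, f-, f0, and a
    per-atom surface area) ingested from upstream electronic-structure output,
    together with numerically encoded Molprint2D circular fingerprints built on
    SYBYL atom types, and classified as SOM or non-SOM with a radial-basis
    support vector machine.  Includes the full evaluation protocol: stratified
    10-fold cross-validation, jackknife (leave-one-out), grid search,
    sensitivity/specificity/accuracy/Matthews correlation, and ROC/AUC, plus a
    synthetic-fixture generator with a planted nucleophilicity signal so the
    whole pipeline is testable without quantum-chemistry runs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    e1071,
    foreign,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
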