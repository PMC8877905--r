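Package: coscreen
Title: Machine-Learning-Assisted Cocrystal Coformer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Virtual screening workflow for pharmaceutical cocrystal coformer
    selection. Provides molecular-formula chemistry (formula parsing, molar
    mass, batch stoichiometry), formula-level molecular descriptors with an
    adapter for external descriptor tables, descriptor-pair classifiers
    (a multilayer perceptron plus random forest, support vector machine and
    gradient boosting baselines) for predicting cocrystal formation of
    API-coformer pairs, the delta-pKa salt/cocrystal/continuum rule, a seeded
    synthetic pair-library generator with a planted hydrogen-bond
    donor-acceptor complementarity signal, ideal-solubility (van't Hoff)
    ranking of solid forms from melting data, and an end-to-end screening
    pipeline with a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    randomForest,
    e1071,
    xgboost,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
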