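Package: copdtriage
Title: Simulation and Evaluation of Machine-Learned COPD Triage Against Physician Consensus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to simulate statistically diverse chronic obstructive
    pulmonary disease (COPD) patient cases from a D-optimal profile design
    completed by correlated Monte Carlo sampling, to label them with a
    configurable synthetic physician panel, to form panel consensus under a
    conservative (higher-category) tie-break, to train and select triage and
    exacerbation classifiers, and to evaluate them with ordinal-safety
    statistics (under-/over-triage, upper-triangular proximity,
    greater-than-one-category error, medical-attention collapse) and a
    panel-size consensus-robustness analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    class,
    e1071,
    glmnet,
    ranger,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr
Config/testthat/edition: 3
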