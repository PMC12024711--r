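Package: traumapolicy
Title: Doubly Robust Policy Trees for Blunt Splenic Trauma Management
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Offline policy learning for the management of blunt splenic
    trauma from observational registry data. Estimates counterfactual
    in-hospital mortality under observation, splenic angioembolization and
    splenectomy with doubly-robust (AIPW) scores built from cross-fitted
    outcome and propensity models, and learns interpretable axis-aligned
    policy trees that prescribe one treatment per leaf to minimize
    estimated mortality. Includes a synthetic trauma-cohort generator with
    a known tree-structured optimal policy for validation, descriptive
    cohort statistics, held-out policy-value evaluation with per-leaf
    reports, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    nnet,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
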