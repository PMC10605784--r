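Package: deltamol
Title: Pairwise Difference (Delta) Machine Learning for Molecular Properties
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curates molecule/property tables, builds leak-free ordered
    molecular pairs, and trains and compares traditional predict-then-subtract
    regressors against direct delta regressors (concatenated-fingerprint
    gradient boosting and a two-encoder directed message passing neural
    network) for predicting molecular property differences. Includes
    invariant diagnostics (self-pair error, swap antisymmetry, triplet
    additivity), a difference-centric evaluation suite with scaffold and
    delta-magnitude stratification, and a synthetic molecule library
    generator with controllable additive ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    Matrix,
    jsonlite,
    ranger,
    stats,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: OpenBabel (obabel on PATH) for batch fingerprinting
RoxygenNote: 7.3.3
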