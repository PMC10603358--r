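Package: blindps
Title: Outcome-Blind Selection of High-Dimensional Propensity-Score Models for Targeted Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for objective selection among Lasso-based propensity-score
    models in high-dimensional healthcare-database studies. Provides a
    synthetic cohort generator emulating linked claims/EHR data (rare binary
    outcome, sparse binary proxy features correlated with latent confounders),
    an outcome-blind (plasmode) simulation framework that bootstraps covariate
    rows and injects known treatment and outcome mechanisms, eight Lasso-based
    propensity-score learners (cross-validated Lasso, outcome-adaptive Lasso,
    collaborative-controlled variants, and their cross-fitted counterparts),
    targeted minimum loss-based estimation (TMLE) of the marginal risk
    difference with influence-curve inference, a bias/MSE/coverage comparison
    harness, and a causal-gap sensitivity analysis with the G-value.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    Matrix,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
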