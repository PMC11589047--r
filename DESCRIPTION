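Package: cifmis
Title: Cumulative Incidence Regression, Estimands and Tests Under
    Misspecification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for treatment-effect analysis of competing-risks data in
    two-arm randomized trials using complementary log-log models for the
    cumulative incidence function (CIF).  Implements Fine-Gray weighted
    pseudo-score estimation and direct binomial regression with
    inverse-probability-of-censoring weighting and robust (sandwich or
    bootstrap) variances, together with deterministic calculators for the
    probability limits (estimands) of both estimators when the true
    data-generating process is an intensity-based or CIF-based competing
    risks model.  Also provides calibrated simulators for both process
    families, classical tests (cause-specific log-rank and Cox Wald tests,
    a joint two-degree-of-freedom Cox test, Gray's test), goodness-of-fit
    checks for a time-constant treatment effect, a Schoenfeld-type
    sample-size formula for subdistribution hazard regression, and a
    seeded Monte Carlo harness for type-I-error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cmprsk,
    graphics,
    survival,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
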