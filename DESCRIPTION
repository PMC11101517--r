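Package: ttemu
Title: Target Trial Emulation of Beta-Blocker Therapy After Myocardial
    Infarction with a Synthetic Registry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for emulating a pragmatic randomized trial of long-term
    beta-blocker therapy after myocardial infarction using registry-style
    observational data.  Includes a synthetic-registry generator with a
    counterfactual oracle (confounded prescribing, refill-based adherence,
    competing death and reinfarction hazards), eligibility and
    prescription-based treatment assignment, pharmacoepidemiologic
    dispensation-coverage and gap-based censoring rules, stabilized inverse
    probability of treatment and censoring weights with balance diagnostics,
    IP-weighted pooled logistic discrete-time hazard models with restricted
    cubic splines for standardized risk curves, risk differences and ratios
    and average hazard ratios, nonparametric bootstrap confidence intervals,
    and a suite of sensitivity analyses including a clone-censor-weight
    analysis of baseline alignment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils,
    withr,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    survival,
    sandwich,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
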