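Package: opioidcf
Title: Counterfactual Modeling of Intraoperative Opioid Exposure and
    Postoperative Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline linking intraoperative opioid bolus records
    to counterfactual predictions of postoperative pain and opioid-use
    outcomes. Converts timestamped IV boluses into effect-site concentration
    exposures with linear compartmental pharmacokinetic models, estimates
    generalized propensity scores for two semicontinuous exposures with
    stabilized weights and percentile trimming, fits weighted outcome models
    (proportional-odds ordinal, two-part hurdle, Cox proportional hazards,
    logistic), and produces g-computation estimates of the population-mean
    outcome change under incremental intraoperative dosing, with bootstrap
    confidence intervals. Includes a synthetic-cohort generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    survival,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
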