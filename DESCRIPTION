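Package: gwgchart
Title: Harmonization, Heterogeneity Assessment, Imputation and Centile
    Estimation for Adolescent Gestational Weight Gain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for constructing gestational weight gain (GWG) reference
    charts for adolescents from multi-country longitudinal antenatal records.
    Provides a synthetic cohort generator emulating a nine-site pooled dataset;
    LMS-based growth-reference z-scores and WHO BMI-for-age classification;
    eligibility filtering with a flowchart-style exclusion ledger and automated
    detection of biologically implausible weight trajectories; Standardized
    Site Difference (SSD) heterogeneity assessment with a small-cell
    sensitivity analysis; first-trimester weight imputation under a
    missing-not-at-random mechanism via the normal linear model with bootstrap,
    pooled by Rubin's rules; and Box-Cox Cole-Green (BCCG/LMS) centile curve
    fitting over gestational age with deviance/AIC/GAIC diagnostics and
    quantile-residual model checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    splines,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
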