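Package: vadcea
Title: Cost-Utility Analysis of Venous Access Devices for Long-Term
    Chemotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Decision-tree cost-utility modelling of the three venous access
    devices used for long-term chemotherapy in breast cancer: central venous
    catheters (CVC), peripherally inserted central catheters (PICC) and
    implantable venous access ports (IVAP). Provides the full analysis chain
    as composable, pipe-friendly functions: a packaged base-case parameter
    set, synthetic patient-cohort simulation with confounded device
    assignment, propensity-score matching with caliper and balance
    diagnostics, parametric catheter-survival fitting with AIC-based family
    selection, estimation of model parameters from patient-level data,
    expected cost and quality-adjusted life-year evaluation per device and
    dwell-time scenario, cost-effectiveness and incremental
    cost-effectiveness ratios with dominance handling, and deterministic
    (tornado) plus probabilistic (Monte Carlo, acceptability-curve)
    sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    flexsurv,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
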