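Package: regretdca
Title: Regret-Based Decision Curve Analysis for Hospice Referral
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for regret-based decision curve analysis (regret DCA)
    applied to the hospice-referral decision for seriously ill patients.
    Elicits a decision maker's threshold probability from dual
    visual-analogue-scale regret ratings (with or without harms of the
    management strategies), re-implements the SUPPORT 180-day survival
    model (physiology score, linear predictor and baseline survival
    table), computes expected-regret curves for the hospice-all,
    treat-all and use-the-model strategies over a threshold grid
    including treatment/hospice effects and prognostic-test harms,
    generates synthetic prediction cohorts with controlled prevalence
    and discrimination, and assembles everything into an end-to-end
    patient recommendation pipeline with frequency-format
    justifications.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
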