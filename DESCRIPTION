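Package: oralscreen
Title: Dual-Mode Oral Cancer Screening Simulation, CNN Triage and
    Diagnostic Accuracy Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying community oral-cancer screening with a
    dual-mode (white-light + autofluorescence) imaging device. Provides a
    synthetic generator for paired WLI/AFI lesion images and multi-tier
    screening cohorts (frontline health worker, onsite and remote
    specialist, biopsy verification), the channel-fusion preprocessing
    that turns an image pair into a three-channel classifier input
    (equalized WLI green and red plus a normalized AFI red/green ratio),
    a compact convolutional classifier trained with focal loss and
    equipped with Monte-Carlo-dropout uncertainty, an uncertainty-threshold
    triage rule with selective referral to a remote specialist, and a
    diagnostic-accuracy layer (sensitivity, specificity, predictive
    values, exact binomial confidence intervals, Cohen's kappa, F1,
    exact non-inferiority sample size) that reproduces tier-versus-tier
    contingency analyses of a field screening study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    png,
    rlang,
    stats,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
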