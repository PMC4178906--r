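Package: pmews
Title: Physiological-Social Modified Early Warning Score for Prehospital Triage
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Implements the physiological-social modified early warning score
    (PMEWS), a banded ordinal triage instrument combining six physiological
    parameters (respiratory rate, oxygen saturation, heart rate, systolic
    blood pressure, temperature, consciousness) with social risk factors
    (age over 65, social isolation, chronic disease) and a 0-4 performance
    status scale. Provides the deterministic scoring engine with an explicit
    band gap-closure rule, diagnostic evaluation of any integer score
    against a binary gold standard (ROC curves, AUROC with DeLong or
    bootstrap confidence intervals, cutoff operating characteristics,
    Youden optimal cutpoints, score-by-disposal tables), descriptive cohort
    summaries, and a latent-severity synthetic cohort generator whose
    parameters are calibrated by derivative-free search so that the scored
    cohort reproduces published summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
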