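Package: subimpute
Title: Subdistribution-Weight Censoring Imputation for Discrete-Time
    Competing Risks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts discrete-time competing-risks survival data into
    single-event survival data by imputing the unobserved censoring times of
    individuals who experienced a competing event first, using subdistribution
    weights derived from a nonparametric life-table estimate of the censoring
    survival function. Includes a simulator for discrete competing-risks data
    generated from a discretized subdistribution hazard model, a reference
    discrete-time logistic hazard learner trained with a two-term
    likelihood-based loss, and evaluation tools (Aalen-Johansen cumulative
    incidence, Kaplan-Meier complement, calibration curves, and an
    inverse-probability-of-censoring-weighted concordance index for competing
    risks).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    cmprsk,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
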