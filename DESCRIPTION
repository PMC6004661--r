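Package: pvsignal
Title: Disproportionality Signal Detection and Onset-Time Analysis for
    Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Case/non-case disproportionality analysis of spontaneous
    adverse-event report databases in the four-table JADER-style layout.
    Builds 2x2 contingency tables for drug (or drug-class) by event
    (MedDRA preferred-term set) pairs, computes the reporting odds ratio
    with Woolf confidence intervals, the proportional reporting ratio,
    the Pearson chi-square statistic, and the Bayesian confidence
    propagation neural network (BCPNN) information component with
    credible bounds; applies signal and inverse-signal detection
    criteria and the ln(PRR)+ln(chi-square) signal value for comparing
    association strength between strata (sex, age). Derives per-report
    time-to-onset with administrative censoring at one year and compares
    onset profiles by Kaplan-Meier estimation and log-rank tests.
    Includes a seeded synthetic report generator with injectable
    reporting-risk multipliers so every pipeline stage is testable
    without access to a real pharmacovigilance database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
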