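Package: cystmisclass
Title: Misclassification Bias from Code-Based Case Assignment in
    Administrative Hospital Data
Version: 0.1.0
Authors@R:
    person("Analytics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates hospitalization-level administrative cohorts with a
    rare three-level surgical outcome (cystectomy with incontinent or
    continent urinary diversion versus no cystectomy), builds and internally
    validates a multinomial logistic prediction model for procedure status,
    assigns case status by procedure codes, by Youden-thresholded predicted
    probability, and by bootstrap imputation, and quantifies the resulting
    misclassification bias of prevalence and association statistics via the
    standardized mean squared error, with ANOVA and Tukey comparison of
    assignment methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
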