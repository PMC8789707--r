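Package: fabnorms
Title: Regression-Based Equivalent-Score Norms for the Frontal Assessment Battery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for regression-based demographic norming of the Frontal
    Assessment Battery (FAB) and its three two-item sub-scales using the
    Equivalent Scores (ES) method: demographic transform selection and
    ordinary-least-squares adjustment equations, non-parametric tolerance
    limits on the 5th centile of adjusted scores, five-level ES
    classification, a scorer preloaded with published Italian adult norms,
    a synthetic-cohort simulator reproducing the normative sample's
    demographic and score structure, and the study-design utilities
    (noncentral-F power analysis for multiple regression, Bonferroni-corrected
    rank-correlation batteries, sex-difference tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse
Config/testthat/edition: 3
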