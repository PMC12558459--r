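Package: keeneye
Title: Dual-Task Computerized Assessment of Visual Hemispatial Neglect
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for a computerized dual-task protocol for diagnosing
    visual hemispatial neglect: reproducible stimulus-schedule generation
    (75-trial main series over 14 screen positions and 25 unilateral or
    bilateral configurations), session response handling, the full error-count
    and asymmetry/productivity/efficiency coefficient scoring scheme,
    threshold and Gini-based classification-tree diagnostic criteria with
    cross-validation, vertical and per-position diagnostic analyses with
    exact nonparametric tests, and a generative patient simulator with
    analytic expected-score oracles for validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    rpart,
    optparse,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
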