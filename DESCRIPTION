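Package: metacheckr
Title: Internal Consistency Checks for Statistical Results Reported in
    Meta-Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scans article text for in-text APA-style null hypothesis
    significance test results (t, F, chi-square, Z, correlation, and the
    meta-analytic Q, Q-between and Q-within heterogeneity tests),
    recomputes each p-value from the reported test statistic and degrees
    of freedom, and classifies every result as consistent, inconsistent,
    or grossly inconsistent with rounding-aware and one-tailed-aware
    logic. Converts PDF, HTML, DOCX and plain-text documents to raw text,
    aggregates document- and corpus-level prevalence and significance-
    direction bias statistics, and ships a seeded synthetic-corpus
    generator that plants results with known error types for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
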