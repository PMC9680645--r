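Package: finpheno
Title: Financial Digital Phenotyping of Mood-Episode Spending Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for N-of-1 financial-behavioral phenotyping
    in bipolar disorder. Parses bank-statement exports that carry
    PDF-extraction artifacts into a clean transaction ledger, applies a
    privacy-preserving transform (description removal, per-account min-max
    normalization), labels transactions with monthly life-chart mood-severity
    ratings, and analyzes the labeled series with burstiness statistics on
    inter-event intervals, Welch one-way ANOVA with Games-Howell post-hoc
    comparisons across symptom phases, and isolation-forest anomaly detection
    on weekly spending frequency. Includes a mood-modulated synthetic ledger
    generator so the full workflow is testable without real financial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    purrr,
    pracma,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    readr,
    ggplot2,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
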