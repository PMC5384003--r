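Package: pindexr
Title: Participation-Index Scoring for Self-Reported Phenotype Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores every phenotype in an open, self-reported cohort by the
    number of participants who validly report it, and every participant by the
    share of total phenotype weight they contribute (the participation index,
    P-index, and its quantitative-trait variant, the QtP-index). Includes the
    survey normalization pipeline (synonym reconciliation, implicit-"no"
    filling for checklist surveys, invalid-value handling), validity filtering
    and ranking, cohort-level analytics (prevalence tables, distribution
    summaries, sex comparison tests, state stratification, zip-code degree-cell
    clustering), a synthetic-cohort generator for end-to-end testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    stats,
    utils,
    tools,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
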