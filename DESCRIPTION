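Package: condgrowth
Title: Conditional Growth Modeling of Infant Anthropometry and
    Neurodevelopmental Delay
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the association between infant physical
    growth and early neurodevelopmental delay in term-born cohorts.
    Implements LMS growth-reference z-scoring with birth stratification by
    parity and gestational week, extrapolation of irregularly timed
    checkup measurements to target ages, conditional growth modeling
    (decorrelated linear growth and relative weight gain), Ages & Stages
    Questionnaires (third edition) scoring with normative cutoffs,
    sex-stratified quasi-Poisson relative-risk regression, cohort balance
    diagnostics, and a seeded synthetic-cohort generator so that every
    stage can be validated without access to restricted cohort data.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    MASS,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
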