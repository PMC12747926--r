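Package: jiaepi
Title: Epidemiology and Biologic Treatment Patterns of Juvenile
    Idiopathic Arthritis from Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for claims-database pharmacoepidemiology of
    juvenile idiopathic arthritis (JIA): cohort identification from diagnosis
    and prescription claims (inpatient/outpatient code criteria plus an NSAID
    exposure criterion), spondyloarthritis-feature subgrouping, annual
    incidence and prevalence estimation with age/sex stratification,
    grace-period exposure-episode construction from prescription fills, a
    continuation/switch/restart/discontinuation classifier for biologic
    treatment courses, and Kaplan-Meier drug survival with Greenwood variance
    and log(-log) confidence intervals. Ships a synthetic claims generator
    with known ground truth so every stage is testable without access to a
    restricted claims database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
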