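Package: apcohort
Title: Antipsychotic Cohort Simulation and Cardiac-Mortality Rate Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates linked primary-care, hospital and death-registry
    records with known treatment effects, and implements a complete
    pharmacoepidemiologic pipeline over them: new-user and psychiatric
    nonuser cohort construction with matched general-population controls,
    time-varying antipsychotic exposure episodes with chlorpromazine-
    equivalent dose standardisation, multi-source adjudication of mortality
    and cardiac outcomes (including three nested sudden-cardiac-death
    definitions with a free-text search), person-time Poisson rate-ratio
    estimation with events-per-parameter-budgeted backward covariate
    selection, and kernel-smoothed hazard-rate curves over treatment time.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
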