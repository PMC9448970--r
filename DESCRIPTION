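Package: skipmark
Title: Multistate Mark-Recapture Analysis of Survival and Reproductive Skipping
Version: 0.1.0
Authors@R:
    person("Penguin", "Datateam", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating apparent survival, encounter and breeding-state
    transition probabilities of individually marked seabirds from annual
    detection records. Implements a three-state (breeder, nonbreeder,
    prebreeder) Arnason-Schwarz multistate model with fixed parameters,
    colony groups and prey-biomass covariates, contingency-table
    goodness-of-fit tests with overdispersion estimation (c-hat), QAICc
    model selection with a stepwise recapture-survival-transition
    procedure, plus a seeded synthetic-data generator and a one-command
    pipeline that turns raw transponder detections into encounter
    histories and demographic estimates.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
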