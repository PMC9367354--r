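Package: herdEV
Title: Stochastic Dairy-Herd Simulation and Economic Values for Breeding Goals
Version: 0.1.0
Authors@R:
    person("herdEV", "Maintainers", email = "maintainers@herdev.invalid",
           role = c("aut", "cre"))
Description: A bio-economic pipeline for deriving marginal economic values
    (EV) of dairy-cattle breeding-goal traits. A stochastic, mechanistic herd
    model simulates a 200-cow herd in weekly steps (milk yield, reproduction,
    disease incidence, mortality, culling and replacement), annual technical
    results are priced into an income/cost statement with a contribution
    margin per cow-year, paired "high"/"low" trait scenarios are compared
    under common random numbers, and EVs are estimated by a multiple
    regression with mediator variables that corrects for double counting
    between correlated traits. Breed calibrations and a price book are read
    from plain-text configuration files; a command-line interface ties the
    stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
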