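Package: endoxsim
Title: Simulation of Endoxifen Target Attainment Under Tamoxifen Dosing
    Strategies and Non-Adherence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico evaluation of tamoxifen dosing strategies for breast
    cancer therapy. Implements a joint parent-metabolite population
    pharmacokinetic model of tamoxifen and its active metabolite endoxifen
    (first-order absorption with lag time, linear formation and elimination,
    CYP2D6 activity-score, age and body-weight covariate effects, log-normal
    interindividual variability), a virtual-patient generator, five dosing
    strategies including model-informed precision dosing with MAP-Bayesian
    forecasting from simulated therapeutic drug monitoring samples, weekly
    missed-dose adherence scenarios, and risk summaries of steady-state
    endoxifen trough target non-attainment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
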