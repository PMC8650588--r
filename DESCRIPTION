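Package: hydrodose
Title: Root-Zone Nutrient Dynamics and Dosing Control for Closed Hydroponics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates macronutrient dynamics in the nutrient tank of a
    closed (emission-free) hydroponic system. Couples Michaelis-Menten root
    uptake kinetics with logistic root growth, a Boltzmann leaf-area-index
    curve and a reduced Penman-Monteith transpiration model in a tank mass
    balance integrated with dosing and replacement events. Provides a
    stochastic weather generator (random-walk cloud cover over a clear-sky
    irradiance model, bounded random-walk vapour pressure deficit), three
    fertigation controllers (volume-, time- and EC+volume-based),
    progress-curve estimation of uptake and transpiration parameters from
    weekly depletion records, optimization of the dosing composition so the
    root-zone composition deviates least from a standard solution, and a
    synthetic-data generator emulating a weekly-replacement depletion
    campaign.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lhs
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
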