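Package: bombusim
Title: Delay Differential Equation Simulator of Bumble Bee Colony Dynamics
    and Pesticide Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a single Bombus terrestris colony over one 120-day
    season with a stage-structured delay differential equation model: in-nest
    nectar and pollen stores, adult workers, and worker, male and gyne larval
    cohorts with fixed development times. Larval ejection (negligence and
    malnutrition) and oophagy regulate the colony through cumulative larval
    mortality integrals, and the model exposes lethal (acute LD50 worker
    cull), sublethal (foraging and egg-laying reduction) and combined
    pesticide-exposure scenarios, with cumulative reproductive output (males
    plus gynes) as the season endpoint. Includes scenario sweep grids, summary
    metrics, YAML configuration and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
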