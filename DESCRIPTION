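Package: foodcge
Title: Stylized Food-System General Equilibrium Model with Environmental
    Satellite Accounts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale computable general equilibrium (CGE) model of a
    small open economy with a disaggregated beef value chain. Provides social
    accounting matrix (SAM) input/output, validation and biproportional (RAS)
    balancing; nested constant-elasticity-of-substitution (CES) production
    and household utility trees calibrated to a benchmark SAM; a damped-Newton
    levels solver and a Johansen/Euler percent-change solver with alternative
    macro closures; beef-replacement scenarios imposed as expenditure-
    preserving preference shifts towards plant-based alternatives or other
    foods; and an environmental satellite account that converts simulated
    sector-output changes into changes in greenhouse gases, blue water,
    nitrogen and phosphorus application, and animal head counts. A seeded
    synthetic-SAM generator emulating the structure of the US food system
    makes every stage runnable and testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
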