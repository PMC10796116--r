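Package: phytoalloc
Title: Proteome Allocation Model of Phytoplankton Thermal Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained proteome allocation model of a generic
    phytoplankton cell. Finds the steady-state resource allocation
    (proteome investment fractions, lipid-flux splits, internal metabolite
    levels and cell geometry) that maximizes growth rate under a given
    temperature, irradiance and nutrient environment, subject to mass
    balances and energy, membrane, space and macromolecular-density
    constraints. Includes Arrhenius thermal kinetics with a photosystem
    damage-repair quasi-steady state, a multistart augmented-Lagrangian
    solver, trait extraction (growth, carbon fixation, carbon use
    efficiency, chlorophyll density, N:C quota, cell size, carbon
    storage, respiratory mode), temperature-sweep and adaptation-scenario
    drivers, and plain-text configuration and result I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    compiler,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
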