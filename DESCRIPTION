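Package: ebrglyc
Title: Kinetic Model of Glycolysis in Ethanol-Consuming Erythrocyte-Bioreactors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for the energy metabolism of
    erythrocyte-bioreactors (red blood cells loaded with alcohol
    dehydrogenase and acetaldehyde dehydrogenase for blood ethanol removal).
    Implements the full kinetic model of erythrocyte glycolysis coupled to
    the encapsulated NAD-consuming enzymes: 15-16 stiff ordinary
    differential equations with conserved adenylate and NAD pools, an
    algebraic adenylate-kinase equilibrium, and mechanistic rate laws for
    all nineteen reactions and transport steps. Provides stiff time
    integration, suspension-level ethanol-consumption simulations,
    steady-state solving with linear stability analysis, one-parameter
    regime scans (stable, oscillatory, metabolite accumulation, loss of
    steady state) with bisection-refined boundaries, and limit-cycle
    quantification (amplitude, period, phase relations among metabolites).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
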