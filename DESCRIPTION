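Package: haloselect
Title: Valence-Bond Barrier Estimation and Rebound Microkinetics for
    Iron(III) Hydroxo-Halide Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the chemoselectivity of ligand-radical
    rebound from cis-Fe(III)(OH)(X) complexes to carbon radicals. Implements
    a valence-bond curve-crossing model that estimates hydroxyl- and
    halogen-transfer barriers from diabatic bond energies, orbital pair
    gaps and a resonance-energy rule; converts stationary-point energy
    landscapes into Eyring rate constants and simulates the bifurcated
    rebound network (reversible halogen transfer in the solvent cage
    versus irreversible hydroxylation) to product distributions; classifies
    outcomes (halogenation, hydroxylation, Bell-Evans-Polanyi compliance,
    equatorial versus distal transfer, isomerisation competitiveness); and
    generates physically ordered synthetic bond-energy tables and
    landscapes for property-based testing and selectivity phase diagrams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
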