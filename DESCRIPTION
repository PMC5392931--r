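Package: ammoflux
Title: Thermodynamics of Ammonia and Ammonium Transport in Yeast Chemostats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of ammonium (NH4+) versus ammonia (NH3) transport
    physiology in Saccharomyces cerevisiae from chemostat and micro-titer
    data. Provides Henderson-Hasselbalch speciation of the total ammonium
    pool, a three-compartment (cytosol, vacuole, mitochondria) equilibrium
    model that deconvolves whole-cell NH_X measurements into free cytosolic
    NH3, mechanism-specific predictions of intracellular/extracellular
    concentration ratios with sensitivity bounds (passive NH3 diffusion
    versus membrane-potential-driven NH4+ uniport), apparent membrane
    permeability estimation from steady-state fluxes and from growth-rate
    dose responses, ATP and yield accounting of chemostat rates, and a
    seeded synthetic-data generator for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
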