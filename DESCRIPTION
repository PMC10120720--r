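Package: retinolBBB
Title: Quantitative Analysis of Retinol Transport Across an In Vitro Blood-Brain Barrier
Version: 0.1.0
Authors@R:
    person("BBB", "Modelling Group", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of retinol (vitamin A) delivery to and
    across brain microvascular endothelial cell (BMEC) monolayers. Implements
    mass-action equilibrium speciation of retinol among its serum carriers (retinol
    binding protein 4 and transthyretin), conversion of liquid-scintillation counts
    (DPM) to molar concentrations, monophasic and biphasic cellular-accumulation
    kinetics with a triggered secondary uptake mechanism, Transwell apparent
    permeability with sampling-withdrawal correction and mass-balance closure, a
    seeded synthetic-data generator for accumulation and Transwell assays, and a
    pipeline runner with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
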