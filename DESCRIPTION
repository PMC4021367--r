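Package: thermoflux
Title: Constraint-Based Flux Analysis of Thermophile Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constraint-based analysis of genome-scale metabolic
    models of thermophilic bacteria such as Thermus thermophilus. Provides an
    S4 model container with gene-protein-reaction (GPR) logic, readers and
    writers for SBML level 2 version 1 and tabular reaction lists, media
    specifications as exchange-flux bounds, flux balance analysis (FBA) and
    flux variability analysis (FVA) on a built-in bounded-variable simplex
    engine, single-gene deletion essentiality screening in multiple media,
    dead-end metabolite and blocked-reaction detection, biomass-equation
    assembly from compositional measurements (amino-acid and fatty-acid mol
    percent, GC content, macromolecule mass fractions), and amino-acid
    supply-versus-demand flux accounting. Ships deterministic synthetic-network
    generators with analytically known optima for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, Matrix, xml2, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'gpr.R'
    'model-core.R'
    'lp.R'
    'io-table.R'
    'io-sbml.R'
    'io-medium.R'
    'flux.R'
    'deletion.R'
    'network-qc.R'
    'biomass.R'
    'compare.R'
    'synthetic.R'
    'fixture.R'
    'pipeline.R'
    'thermoflux-package.R'
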