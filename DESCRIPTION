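Package: nanaerobics
Title: Bioenergetics and Meta-Omic Profiling of Nanaerobic Methanogenic Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating nanaerobic digestion: a microbial
    bioenergetics engine for the acetate-to-methane pathways (standard,
    temperature-corrected and condition-specific Gibbs free energies,
    thermodynamic threshold solving and H2/CO2 constraint grids), a
    terminal-oxidase gene and transcript profiling workflow with
    housekeeping-gene normalization of metagenome and metatranscriptome
    counts, methane-correlation statistics, and a negative-binomial
    synthetic-data generator emulating ecosystem-specific gene catalogs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
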