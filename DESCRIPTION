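Package: phenoarray
Title: Quantitative Image Analysis for Phenotypic RNAi Cell Microarrays
Version: 0.1.0
Authors@R:
    person("Phenoarray", "Developers", email = "maintainer@phenoarray.dev",
           role = c("aut", "cre"))
Description: Tools for planning, simulating and quantifying reverse-transfection
    cell microarrays ("phenotypic microarrays"). Plans printable spot grids and
    multi-array library partitions, computes transfection-recipe payload
    concentrations and Ct-based relative expression, simulates ground-truthed
    three-channel fluorescence fields (tracer, phenotype, nuclei) of cell
    monolayers over printed spots, detects and registers spots, segments nuclei
    by distance-transform watershed, scores per-cell phenotype expression,
    assigns cells to spots, and reports control-normalized percent-expressing
    cells with knockdown statistics. Includes readers and writers for 8/16-bit
    grayscale TIFF, GenePix Array List (GAL) dialect layouts and CSV tables,
    plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
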