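Package: SSStest
Title: Detection of Lineage-Specific Selection on RNA Secondary Structure
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical testing for lineage-specific positive selection
    acting on RNA secondary structure. Given a family of orthologous RNA
    sequences, each species is tested in turn as the focal lineage: the
    structural impact of its substitutions and indels relative to the
    background consensus is scored against an empirical null model based
    on base-pair probability matrices, corrected for multiple testing,
    and aggregated into a selection score (the SSS-score). The package
    also provides structural family-divergence estimation, extraction of
    orthologous local structure blocks from long RNAs, a synthetic
    RNA-evolution simulator for benchmarking under negative, neutral and
    positive selection regimes, and shuffle-based false discovery rate
    estimation. Thermodynamic folding is delegated to the ViennaRNA
    package programs, which must be installed and on the search path.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
SystemRequirements: ViennaRNA (RNAfold, RNAalifold, RNALfold on PATH);
    optionally an external multiple sequence aligner such as mafft or
    muscle for unaligned input
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'utils.R'
    'config.R'
    'alignment-io.R'
    'folding.R'
    'variants.R'
    'discrepancy.R'
    'tree-edit.R'
    'indels.R'
    'scoring.R'
    'divergence.R'
    'run-family.R'
    'local-blocks.R'
    'evolve.R'
    'fdr.R'
    'report.R'
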