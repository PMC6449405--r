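Package: hicdyn
Title: Chromatin Architecture Dynamics from Binned Hi-C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of chromatin-architecture dynamics across a
    differentiation time course from binned Hi-C contact matrices:
    iterative-correction (ICE) balancing, observed/expected normalization,
    A/B compartment calling by the leading eigenvector of the contact
    correlation matrix, compartment-switch classification across time points
    by one-way ANOVA, saddle-plot compartmentalization and
    compartment-stratified distance-decay curves, TAD boundary detection by
    directionality index and insulation score with cross-sample boundary
    comparison, per-locus trans-contact Z-scores and a chromosome-matched
    permutation test for trans-interacting gene sets, generic category
    enrichment for gene and interval sets, and statistics on 3D DNA FISH
    spot tables (volume-normalized distances, proximity and overlap calls).
    Includes a synthetic-data generator that emits every input format with
    known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
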