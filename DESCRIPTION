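Package: methclean
Title: Quality Control, Normalization and Cross-Tissue Concordance for
    Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for cleaning Illumina 450K-style DNA
    methylation data from paired blood and cerebrospinal-fluid samples:
    detection p-values and sample-level quality flags, normal-exponential
    background and dye-bias correction, control-probe functional
    normalization, sequential probe-level filters, reference-based
    cell-type deconvolution, surrogate-variable adjustment evaluated by a
    permuted-trait null EWAS and the genomic inflation factor, and
    within-CpG / within-individual cross-tissue concordance stratified by
    genomic region and gene orientation. Includes a synthetic-data
    generator that emulates the longitudinal two-tissue plate design
    (checkerboarded trait assignment, fixed-methylation control samples,
    technical replicates) with recorded ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    sva,
    quadprog,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
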