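Package: mcsd
Title: Multi-Class Compressed-Sensing Detector for Molecular Subtype
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Classifies disease subtypes from one or several cascaded
    expression data types (e.g. miRNA and mRNA profiles of the same
    patients) with a multi-class compressed-sensing detector (MCSD).
    Informative probes are scored by five group statistics, a sparse
    compress matrix is learned row-by-row via l1-minimization (basis
    pursuit solved by a homotopy/least-angle path), and samples are
    classified in the compressed space by a Bayesian ideal observer with
    Gaussian class-conditional densities and a configurable utility
    matrix.  Includes readers/writers for tab-separated expression
    matrices, a synthetic multi-block data generator with planted
    class-discriminative features, balanced-split stability experiments,
    a feature-count sweep, model serialization, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
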