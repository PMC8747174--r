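Package: mirprof
Title: Small-RNA miRNA Discovery, Annotation, Target Prediction and qPCR
    Quantification for Plant sRNA-Seq Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, fully scriptable pipeline for microRNA profiling
    of plant small-RNA sequencing libraries: adapter trimming, quality and
    length filtering, unique-tag collapsing and ncRNA contaminant removal;
    conserved-miRNA annotation by ungapped homology against a mature
    reference set with a configurable mismatch budget; novel-miRNA discovery
    by genome mapping, precursor excision, secondary-structure folding,
    stem-loop criteria and the minimal folding free energy index (MFEI);
    plant-mode and animal-mode (cross-kingdom) target prediction with
    cleavage/translational-repression mode calling and MFE-weighted network
    export; and qPCR relative quantification by the 2^-ddCt method with
    ANOVA/Tukey compact-letter grouping. Ships a seeded synthetic-data
    generator that plants conserved miRNAs and designed hairpin precursors
    so every stage can be validated against ground truth, plus transcribed
    worked-example tables from a curry-leaf (Murraya koenigii) miRNA survey.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
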