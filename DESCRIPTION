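Package: mitoscreen
Title: Multiomic Screen Statistics for Mitochondrial Stress Recovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistics and simulation tools for multiomic screens of
    mitochondrial stress recovery in yeast. Implements differential-abundance
    testing with the |log2 FC| > 0.7 and P < 0.05 significance rule,
    Perseus-style down-shifted normal imputation, Fisher exact mitochondrial
    enrichment, strain clustering, an average-rank Spearman correlation score
    for linking proteins to depleted triacylglycerol species, 13C-oleate
    isotopologue label accounting with internal-standard and T0 normalization,
    lipidomics feature quality filters, organelle volume fractions from
    confocal z-stacks under a prolate-ellipsoid cell model, respiratory
    growth-curve phenotyping, and seeded synthetic-data generators with
    planted ground truth for every input type.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    tiff,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
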