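Package: coupling3c
Title: Pairwise Analysis of Meiotic Centromere Coupling from 3C-qPCR Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying non-homologous centromere coupling in budding
    yeast from chromosome conformation capture qPCR (3C-qPCR) experiments with a
    double-digestion design (3C2D). Converts raw Taqman crossing-point records,
    random-ligation control libraries and loading-control dilution series into
    normalized 16x16 centromere interaction matrices; provides in-silico
    restriction digestion and assay-design checks; rank, binned-score and
    difference-matrix descriptive analyses; chromosome-size-similarity
    permutation tests with matrix-randomization nulls and their sensitivity,
    subset, avoidance, cluster and cross-strain overlap variants; Fisher's exact
    statistics for cytological spread counts; and a synthetic-data generator
    that simulates centromere coupling as weighted perfect matchings and emits
    every input format the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    Rcpp,
    jsonlite,
    yaml,
    Biostrings,
    pheatmap
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
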