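Package: jellymir
Title: Small RNA Cleaning, miRNA Hairpin Discovery, Digital Expression and
    Target Prediction for Royal Jelly Sequencing Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested reimplementation of a comparative small-RNA and
    transcriptome analysis of honey bee royal jelly: classification and
    filtering of raw small-RNA reads into standard discard categories,
    collapsing to unique tags and genome mapping with at most one mismatch,
    hairpin-based miRNA candidate discovery by minimum-free-energy folding
    of 100-nt genomic windows under a simplified nearest-neighbour energy
    model, digital gene expression testing with the Audic-Claverie exact
    statistic, RPKM normalisation and Benjamini-Hochberg FDR, and
    miRNA:mRNA duplex minimum-free-energy target prediction. A synthetic
    data generator with full truth tables stands in for the study's
    undeposited raw sequencing, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
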