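Package: graphRNA
Title: Noncoding RNA Homology Search in Hybrid Metagenome Assembly Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds a hybrid assembly graph from metagenomic short reads by
    merging an exact-overlap string graph with unitig contigs extracted from a
    de Bruijn graph, then detects and quantifies reads belonging to noncoding
    RNA families by anchor-based homology search over graph paths. Family
    models are structure-aware profiles built from Stockholm alignments and
    aligned by a nested-pair SCFG dynamic program. Includes a synthetic
    community simulator with planted family instances, ground-truth labelling,
    and precision/recall/ROC evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Metagenomics, Alignment, Assembly, RNA
RoxygenNote: 7.3.3
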