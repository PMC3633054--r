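Package: barcodecmp
Title: Compression-Based Distances for DNA Barcode Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Alignment-free phylogenetic analysis of short DNA barcode
    (COI-type) sequences using compression-based distances. Implements a
    dictionary (LZ) DNA compressor providing plain, concatenated and
    conditional compressed sizes; the Normalized Compression Distance (NCD)
    and the Information-Based Distance (IBD); five classical evolutionary
    distance estimators (Kimura 2-parameter, Tajima-Nei, Tamura 3-parameter,
    Tamura-Nei and Maximum Composite Likelihood); distance-based tree
    inference (neighbor joining and UPGMA); Robinson-Foulds and
    edge-matching topology-similarity scores between trees; and a full
    simulation protocol (Yule species trees, multispecies-coalescent gene
    trees, branch-length noise, HKY sequence evolution) together with an
    orchestrator that compares compression-based and evolutionary trees over
    replicated simulated barcode datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
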