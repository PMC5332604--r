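Package: evgtools
Title: Environmental Viral Genome Catalogs, Proteomic Trees, and Genomic OTUs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for turning marine virome assemblies into
    complete viral genomes and genome-based ecology. Implements circular
    (complete) contig detection from terminal repeats, read quality control,
    SNP calling and nucleotide diversity from high-quality pileups, genome
    dereplication, a genome-wide translated-alignment similarity score (S_G)
    with BIONJ proteomic trees and midpoint rooting, genomic OTU delineation
    by average-linkage clustering with adjusted-Rand-index cutoff selection,
    host-group prediction from precision curves, gene-level colinearity via
    bidirectional best hits, and FPKM-based abundance and read recruitment.
    Ships a synthetic viral community generator with planted truth so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    igraph,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vegan,
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
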