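Package: musicmap
Title: Single-Cell Multiplex Chromatin and RNA Interaction Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested reimplementation of the MUSIC (multinucleic acid
    interaction mapping in single cells) data-processing pipeline: simulation
    of barcoded paired-end reads with known ground truth, demultiplexing of
    the three-round split-pool cell barcodes, droplet (GEM) barcodes and I7
    indices, RNA/DNA linker classification, insert trimming, exact mapping on
    synthetic genomes, PCR-duplicate removal, assembly of reads into
    molecular-complex clusters, size-normalized decomposition into pairwise
    contacts, binned contact maps and distance-decay statistics, RNA
    attachment tracks and XIST-chromosome X analytics, per-cell local
    chromatin structure erosion scores and transcriptomic age, and
    association tests between cell-type-specific eQTL-target pairs and
    chromatin contacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse
Config/testthat/edition: 3
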