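Package: hicdecon
Title: Metagenome Deconvolution from Hi-C Proximity-Ligation Read Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for binning metagenome assembly contigs into
    species- and cell-level groups using Hi-C proximity-ligation read
    pairs. Builds length-normalized contig association matrices from
    paired alignments, clusters them with a sparse Markov Clustering
    (MCL) implementation, associates plasmids with their host
    chromosomes, evaluates cluster solutions against ground-truth labels
    with size-weighted pair sampling, renders binned contact maps with
    log and Spearman-rank transforms, and quantifies strain-level signal
    through the connectivity of SNP variant graphs. Includes a synthetic
    microbial community simulator (genomes, restriction maps, contigs,
    Hi-C and mate-pair links) so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
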