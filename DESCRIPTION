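Package: panMGE
Title: Mobile Genetic Element Discovery and Sublineage Delimitation in
    Bacterial Species Complexes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrated comparative genomics of closely related bacterial
    strains: pairwise genome relatedness (fragment-based average nucleotide
    identity and digital DNA-DNA hybridization) with species and sublineage
    delimitation, synteny-block coverage, reciprocal-best-hit pangenome
    clustering with core/flexible/exclusive compartments, seed-driven
    discovery and reconstruction of integrated mobile genetic elements
    (genomic islands, integrative conjugative elements, transposons) from
    draft genomes with att-site direct-repeat recovery, episomal element
    handling (contig circularization, oriV motif scan, in-silico restriction
    digestion and PCR), and insertion-sequence transposition tracking across
    serial-passage resequencing. A synthetic-data forge generates
    ground-truthed two-sublineage species complexes with planted elements so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
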