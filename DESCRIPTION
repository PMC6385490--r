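Package: retrotrace
Title: Retrocopy Translocation, Intron Loss and Promoter Carry-Over Across a
    Species Tree
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomic inference of retrocopy-mediated gene
    translocation for a focal multi-exon gene family across a clade of
    annotated genomes.  Provides splice-aware in-silico cloning of coding
    sequences onto genomic loci under the GT-AG rule, graded classification
    of pseudogenized vestiges, flanking-gene synteny slots and
    species-by-slot presence matrices, irreversible-loss and Dollo parsimony
    placement of intron-loss and translocation events on branches of a
    rooted species tree, promoter motif scanning with carry-over tests and a
    neighbor-joining tree of upstream regions, and a seeded forward
    simulator of a miniature clade with planted retrocopy, pseudogenization
    and erasure events for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    Rcpp,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
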