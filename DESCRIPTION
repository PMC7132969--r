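Package: exonscout
Title: Discovery and Characterization of Unannotated Exons from Spliced
    RNA-Seq Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transcribed islands inside annotated introns from
    spliced RNA-seq alignments, links them to known exons through
    splice-junction read evidence, classifies them (first, internal,
    terminal or unlinked exons) and reconstructs guided transcript
    variants over a splice graph. Quantifies genotype-dependent
    expression of the called regions by RPKM-style read densities and by
    the 2^-ddCt relative qPCR method, and characterizes them
    evolutionarily (sliding-window conservation over a multi-species
    alignment, neighbor-joining phylogeny) and epigenetically
    (hypomethylated-region overlap). Ships a synthetic-locus simulator
    with full ground truth so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    ape,
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
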