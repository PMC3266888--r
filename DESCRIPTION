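Package: lamquant
Title: Quantification and Quality Control for 3'-Biased Low-Input RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for quantifying and quality-controlling amplified,
    3'-biased RNA-seq data from very low input material such as
    laser-microdissected single cell types. Implements multi-mapped read
    weighting by local unique-read coverage and shared splice junctions,
    classification of weighted hits into genomic categories (exon/junction,
    intron, locus-flanking, transposable element, intergenic), a two-step
    3'-anchored locus quantification with proportional redistribution of
    ambiguous hits, replicate concordance metrics for expression vectors and
    assembled locus sets, one-sided Fisher enrichment of protein-domain
    (InterPro) combinations with lowest-term pruning, and SOLiD colorspace
    read prefiltering with double encoding for de novo assembly. A seeded
    synthetic-fixture generator produces toy genomes, annotations, 3'-biased
    spliced alignments and colorspace reads with ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
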