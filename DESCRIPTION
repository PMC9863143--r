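Package: castile
Title: Cas9 Tiling Panel Design and Evaluation for Targeted Nanopore
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for enriching very large genomic regions (hundreds of
    kilobases) by CRISPR/Cas9 tiling ahead of nanopore sequencing. Covers
    the full desk workflow: enumeration and filtering of SpCas9 guide
    candidates against gene annotation, short-read coverage and known
    variants; partition of a region of interest into overlapping ~50-kbp
    sub-regions excised by flanking guide pairs, with conflict-free
    assignment of guides to reaction pools; enrichment and sequencing QC
    (on-target fraction, per-base coverage, read N50, fold enrichment,
    genotypability); comparison of a reconstructed contig against a
    reference region (alignment identity from the NM tag, SNV/indel/SV
    extraction from CIGAR strings, gene-overlap summaries, divergent-region
    detection); and a seeded simulator producing references, diverged
    haplotypes with truth variants, Cas9-digested fragments and
    nanopore-like or Illumina-like reads so that the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
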