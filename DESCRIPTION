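Package: uvmutspec
Title: UV-Induced Mutation Spectrum Analysis from Whole-Genome Resequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for ultraviolet-mutagenesis screens read out by
    whole-genome resequencing of mutant panels against a reference assembly.
    Computes strand-collapsed single-base substitution spectra, per-centre
    transition fractions, trinucleotide-context standardized mutation
    frequencies (n/N x 10^6), adjacent tandem-mutation typology with the
    Watson-Crick bond-change feature, per-contig mutation distribution
    summaries and uniformity diagnostics, genic-region annotation
    (intergenic, intron, synonymous/non-synonymous exon, core promoter),
    a 2x2 contingency test for 3'-neighbour effects on adenine transversion,
    and a canonical k-mer set-difference screen for large (>= 200 bp)
    fragment deletions. Includes a synthetic-data generator producing
    genomes, gene models, mutant SNV sets, tandem events, deletions and
    sequencing reads with planted ground truth, so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
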