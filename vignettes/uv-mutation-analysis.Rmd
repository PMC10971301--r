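---
title: "Methods: UV mutation-spectrum analysis with uvmutspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: UV mutation-spectrum analysis with uvmutspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvmutspec)
library(dplyr)
```

## The setting

A UV mutagenesis screen irradiates genetically uniform propagules (spores,
oidia, cells), recovers survivors at a chosen lethality, and resequences a
panel of independent mutants against the parental assembly. After
alignment and SNP calling — done upstream with the usual BWA/GATK stack —
the analysis input is, per mutant, a set of single-nucleotide variants,
plus the reference FASTA and (predicted) gene models. `uvmutspec` covers
everything downstream of variant calling: spectra, sequence-context
statistics, tandem events, genomic distribution, functional regions, one
targeted association test, and a k-mer screen for fragment deletions.

Coordinates are 1-based and fully closed throughout (the VCF/GFF
convention); BED exports convert to 0-based half-open on the way out.

## Variant intake and hard filters

`read_snvs()` keeps biallelic single-nucleotide records and counts
everything else (indels, multi-nucleotide alleles) as skipped, so the
record set downstream is exactly the unit every table counts: one
(mutant, contig, position, ref, alt) substitution. `validate_records()`
enforces agreement between the VCF reference allele and the genome; a
mismatch is an error by default because it almost always signals a
mismatched reference build, but it can be downgraded to warn-and-drop.

`apply_hard_filters()` reimplements the conventional GATK-style
hard-filter conditions (fail when any holds):
`QD < 2.0`, `MQ < 40.0`, `FS > 60.0`, `SOR > 3.0`,
`MQRankSum ≤ bound`, `ReadPosRankSum ≤ bound`. The rank-sum bounds
default to +12.5/+8.0; GATK's customary bounds are −12.5/−8.0 and are one
call away (`gatk_hard_filter_thresholds()`). Both conventions circulate
in the literature, so neither is guessed: the default follows the screen
protocol this package models, the preset follows GATK, and the choice is
explicit in the report. A missing annotation leaves its condition
unevaluated rather than failing the site, and every triggered condition
is listed, which makes the filter monotone: adding a failing metric can
never rescue a site.

Sites recurring in several mutants count once per (mutant, contig,
position); cross-mutant deduplication is deliberately not applied, since
independent mutants hitting one position are independent mutation events.

## Strand collapsing and the spectrum

Double-stranded DNA gives every substitution two equivalent readings;
`collapse_substitution()` canonicalizes on an A or C centre (complementing
both alleles when the reference base is G or T), yielding six paired
classes labelled `G:C→A:T`, `A:T→G:C`, `A:T→T:A`, `G:C→T:A`, `A:T→C:G`,
`G:C→C:G`. A and C centres (rather than the purine convention) keep the
class labels aligned with how UV work is usually tabulated. Percentages
are rounded to two decimals only in reports; proportions keep full
precision. `transition_fraction()` conditions on the centre: for A it is
`A:T→G:C` over all A-centred classes, for C `G:C→A:T` over all C-centred
classes, `NA` on an empty denominator.

## Context statistics

For each record, `extract_context()` reads both flanking bases and, for
G/T-centred sites, reverse-complements the local triplet so flanks swap
sides consistently with the collapsed centre. Contig-edge sites have no
defined flank; they are flagged, counted, and excluded from motif tallies
rather than imputed.

The *standardized mutation frequency* for a motif is `f = n/N × 10⁶`:
mutated occurrences over genome-wide occurrences, per million. Because
the mutation universe is strand-collapsed, `N` is counted on **both
strands** (forward scan of the motif plus forward scan of its reverse
complement; overlapping occurrences all count). Counting on both strands
is the only convention consistent with collapsed `n` — a C→T at a site
whose motif lies on the minus strand contributes to `n`, so its motif
occurrence must contribute to `N`. Forward-only counting remains
available as a switch for comparison with forward-only tabulations.
A palindromic motif (e.g. TA) is counted once per strand, i.e. twice per
forward occurrence; this is deliberate and matches the collapsed-universe
bookkeeping. `N = 0` propagates as `NA` with a warning, never as
infinity.

## Tandem mutations

`find_tandems()` scans each mutant's sorted positions per contig for
maximal runs of adjacent mutated bases. Runs of exactly two form a tandem
mutation; runs of three or more are reported separately and excluded from
the four-class tally (they are a different, rarer lesion class and
folding them in would silently distort the counts). Per position, a
substitution is a transition iff its ref/alt pair is {A,G} or {C,T}; the
four-way class combines the two positional labels. Tandem motifs are kept
on the reference forward strand, uncollapsed — the tandem literature
tabulates them that way, and the classification is demonstrably not
strand-invariant (a 3′-side transition read from the other strand is a
5′-side transition), which the test suite asserts as a regression.

The bond-change feature of the 5′ substitution asks whether the
Watson–Crick pairing bond number changes (A/T pairs two hydrogen bonds,
G/C pairs three): A↔T and C↔G substitutions preserve it, all others
change it. This is the discriminator separating the frequent 3′-side
transitions (5′ A→T/T→A, no bond change) from the rare ones.

Tandem member sites remain in the single-site record set — a tandem is
two substitutions, and the per-site tables count substitutions.

## Distribution on contigs

`contig_summary()` reports every contig including empty ones; average
spacing is contig length over site count rounded to the nearest integer,
`NA` for empty contigs. `uniformity_test()` makes the usual "non-random
distribution" claim checkable: contigs are tiled with fixed-size bins
(last partial bin kept, length-weighted), per-bin counts are tested
against the length-proportional expectation with a Pearson
goodness-of-fit statistic on `bins − 1` degrees of freedom. The p-value
is asymptotic; with 10 kb bins and a few thousand sites expected counts
are comfortably above the usual rule-of-thumb. Under a uniform null the
p-values are uniform, which the suite checks by simulation (100
replicates, Kolmogorov–Smirnov).

## Region annotation

`annotate_sites()` assigns each record one of: CDS exon (then synonymous
vs non-synonymous by translating the affected codon with the standard
genetic code, on the coding strand, honouring CDS phase), intron (inside
the gene span, outside CDS), core promoter — defined as the 200 bases
immediately 5′ of the start codon on the coding strand, truncated at
contig ends — or intergenic. Precedence on overlap is
CDS > intron > promoter > intergenic; overlapping genes tie-break on the
lexicographically smallest gene id, deterministically.

Ab-initio fungal gene predictors emit CDS-only models, so UTR exons do
not normally arise. When a site falls in a partial codon at a model edge
it stays exonic with `NA` codon change under the label
`exon_undetermined`, reported in its own summary row and excluded from
the five-way proportions with a warning — never silently folded into a
class, so five-way tables stay comparable across gene-model sources.

## The 3′-neighbour association test

`build_contingency()` restricts to A-centred records of class A→G or A→T
(A→C is excluded by design — the question is transition vs the
T-transversion) and splits the collapsed 3′ neighbour into purines (A+G)
vs pyrimidines (T+C). `pearson_chi_square()` uses the 2×2 closed form
`X² = N(ad−bc)²/(r₁r₂c₁c₂)` with one degree of freedom. No continuity
correction by default — at the cell sizes such screens produce it is
immaterial — with Yates available as a flag. The p-value is reported in
scientific notation; displays that print "0.000" are formatting, not a
value this package will emit.

## The k-mer deletion screen

`kmer_set()` extracts every k-window without N and canonicalizes
(lexicographic minimum of the k-mer and its reverse complement), making
sets strand-independent. For read input, k-mers below a multiplicity
floor (default 2) are dropped first — the standard guard against
sequencing-error k-mers; for assembled input the floor is 1. The screen
takes the set difference *wild-type minus mutant*: k-mers spanning a
deleted interval exist in the wild type only.

`call_deletions()` anchors each exclusive k-mer at its unique reference
position (k-mers occurring more than once in the genome are dropped —
repeats cannot be anchored), merges anchors whose start gaps are at most
`max_gap` (default `k`, bridging anchors lost to repeats) and estimates
the deleted interval by trimming `k − 1` from the left of the anchor
span: a deletion of bases `s..e` makes exactly the k-mers starting in
`s−k+1 .. e` exclusive, so `start = first anchor + k − 1`,
`end = last anchor`. Anchors lost to repeats erode the interval inward,
bounding each breakpoint error by `k − 1`. Intervals shorter than
`min_length` (default 200 bp, the screen's detection floor) are
discarded; an isolated SNV produces an anchor run that collapses to ~1 bp
and vanishes at this step, which is what makes the screen specific to
fragment deletions. Defaults `k = 31`, `max_gap = k` and the count floors
are engineering choices documented here, not inferences about any
upstream service.

## The synthetic-data generator

The generator exists so that every stage has planted ground truth:

* `sim_genome()` — i.i.d. bases at a target GC (default 0.48, a typical
  agaric assembly); contig count and lengths free.
* `plant_gene_models()` — non-overlapping single-exon CDS models (ATG,
  stop-free body, terminal stop), random strand, 250 bp clearance for
  promoters; the CDS-only shape ab-initio predictors emit.
* `sim_mutants()` — per-mutant SNV positions drawn without replacement;
  classes drawn from six class weights whose defaults are the canonical
  UV spectrum (dominant G:C→A:T, ratios ≈ 60.4 : 17.6 : 10.6 : 6.0 :
  3.6 : 1.8); optional 5′-flank bias via rejection sampling (simple and
  exact, at the cost of rejections, rather than building a genome-wide
  weighted sampler); accidental adjacencies pruned so planted tandem
  counts are exact; tandem events planted per class; deletions excised
  from per-mutant genome copies that also carry the mutant's SNVs.
* `sim_reads()` — uniform single-end reads from both strands with i.i.d.
  substitution errors.

All randomness flows from explicit seeds; `sim_bundle()` writes a
complete on-disk fixture (FASTA, GFF3, per-mutant VCFs, FASTQ, truth
TSVs) byte-identically reproducible from its seed.

What the generator does *not* emulate: coverage bias, indel and CNV
realism, quality-score models, linked or recurrent mutation processes,
real repeat structure. Passing recovery tests on synthetic data therefore
demonstrates correctness of the bookkeeping and the estimators under the
stated model, not robustness to every artefact of real libraries —
repeat-dense genomes in particular will erode deletion-screen anchors
faster than the i.i.d. genome suggests.

## Problem sizes and numerical choices

The test and reproduction scripts run the stochastic recoveries at panel
scale (100 mutants, 3707 sites on a 300 kb genome) and the deletion
screen on a 50 kb genome at 30× error-free coverage with planted 720,
290/300 and 150 bp deletions — sizes chosen so the statistical behaviour
(multinomial recovery within binomial error, breakpoint error ≤ k−1,
rejection below the 200 bp floor) is already in its asymptotic regime
while a full run stays in seconds. Tolerances in the suite are derived,
not tuned: binomial 3σ for class-proportion recovery, `k − 1` for
breakpoints, `1e−9` for algebraic identities between the closed-form and
expected-count chi-square.

Degenerate inputs are contracts, not corner cases: empty record sets
yield zero-count tables with `NA` proportions; zero marginals refuse the
chi-square with a warning; `N = 0` motifs propagate `NA`; genomes must be
pure A/C/G/T/N and fail loudly otherwise.
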