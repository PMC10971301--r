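# Hand-built contig: filler, then a + strand single-exon gene at 301-312
# (ATG GAA CCC TAA), then a + strand two-exon gene with CDS 601-612 and
# 701-712 (intron 613-700).
region_fixture <- function() {
  filler <- strrep("AC", 150)          # 1-300
  cds1 <- "ATGGAACCCTAA"               # 301-312
  mid <- strrep("GT", 144)             # 313-600
  exon1 <- "ATGCCCGGGAAA"              # 601-612; intron 613-700; exon2 701-712
  intron <- strrep("T", 88)            # 613-700
  exon2 <- "CCCGGGAAATAA"              # 701-712
  tail <- strrep("CA", 144)            # 713-1000
  seq <- paste0(filler, cds1, mid, exon1, intron, exon2, tail)
  stopifnot(nchar(seq) == 1000)
  genome <- tiny_genome(c(c1 = seq))
  models <- tibble::tibble(
    gene_id = c("gA", "gB", "gB"),
    contig = "c1", strand = "+",
    start = c(301L, 601L, 701L),
    end = c(312L, 612L, 712L),
    phase = 0L)
  list(genome = genome, models = models)
}

test_that("sites are classified with the documented precedence", {
  fx <- region_fixture()
  rec <- make_records("c1",
                      c(49,   250,  306,  305,  650),
                      c("A",  "C",  "A",  "A",  "T"),
                      c("G",  "T",  "G",  "T",  "C"))
  ann <- annotate_sites(rec, fx$models, fx$genome)
  expect_equal(ann$region,
               c("intergenic", "core_promoter", "exon_synonymous",
                 "exon_nonsynonymous", "intron"))
  # GAA -> GAG is E -> E; GAA -> GTA is E -> V
  expect_equal(ann$ref_codon[3], "GAA")
  expect_equal(ann$alt_codon[3], "GAG")
  expect_equal(ann$ref_aa[3], "E"); expect_equal(ann$alt_aa[3], "E")
  expect_equal(ann$alt_codon[4], "GTA")
  expect_equal(ann$alt_aa[4], "V")
  expect_equal(ann$gene_id[5], "gB")
})

test_that("core promoter spans 200 bp upstream of the start codon", {
  fx <- region_fixture()
  # gA starts at 301: promoter is 101-300
  at <- function(p) {
    ref <- substr(as.character(fx$genome[[1]]), p, p)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    annotate_sites(make_records("c1", p, ref, alt), fx$models,
                   fx$genome)$region
  }
  expect_equal(at(101), "core_promoter")
  expect_equal(at(300), "core_promoter")
  expect_equal(at(100), "intergenic")
})

test_that("minus-strand codons are translated on the coding strand", {
  # reverse-complement the fixture: coordinates mirror, strands flip
  fx <- region_fixture()
  L <- 1000L
  seq_rc <- rc_oracle(as.character(fx$genome[[1]]))
  g2 <- tiny_genome(c(c1 = seq_rc))
  m2 <- fx$models %>%
    dplyr::mutate(start2 = L - end + 1L, end2 = L - start + 1L,
                  strand = "-") %>%
    dplyr::select(gene_id, contig, strand, start = start2, end = end2,
                  phase) %>%
    dplyr::arrange(contig, start)
  # the site 306 A->G (synonymous) maps to L-306+1 = 695, T->C
  ann <- annotate_sites(make_records("c1", 695L, "T", "C"), m2, g2)
  expect_equal(ann$region, "exon_synonymous")
  expect_equal(ann$ref_codon, "GAA")
  expect_equal(ann$alt_codon, "GAG")
})

test_that("region calls partition the record set and fold to intergenic", {
  g <- sim_genome(c(c1 = 30000L), gc = 0.5, seed = 61)
  pl <- plant_gene_models(g, 10, 300L, seed = 62)
  sim <- sim_mutants(pl$genome, n_mutants = 3, snvs_per_mutant = 50,
                     seed = 63)
  ann <- annotate_sites(sim$records, pl$models, pl$genome)
  s <- suppressWarnings(region_summary(ann))
  expect_equal(sum(s$count), nrow(sim$records))
  # no models -> everything intergenic
  none <- annotate_sites(sim$records, pl$models[0, ], pl$genome)
  expect_true(all(none$region == "intergenic"))
})

test_that("region calls survive reverse-complementing the genome", {
  g <- sim_genome(c(c1 = 20000L), gc = 0.5, seed = 71)
  pl <- plant_gene_models(g, 6, 300L, seed = 72)
  sim <- sim_mutants(pl$genome, n_mutants = 2, snvs_per_mutant = 30,
                     seed = 73)
  ann <- annotate_sites(sim$records, pl$models, pl$genome)

  L <- 20000L
  g_rc <- tiny_genome(c(c1 = rc_oracle(as.character(pl$genome[[1]]))))
  m_rc <- pl$models %>%
    dplyr::mutate(start2 = L - end + 1L, end2 = L - start + 1L,
                  strand = ifelse(strand == "+", "-", "+")) %>%
    dplyr::select(gene_id, contig, strand, start = start2, end = end2,
                  phase) %>%
    dplyr::arrange(contig, start)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rec_rc <- sim$records %>%
    dplyr::mutate(pos = L - pos + 1L, ref = unname(comp[ref]),
                  alt = unname(comp[alt]))
  ann_rc <- annotate_sites(rec_rc, m_rc, g_rc)
  ord <- order(sim$records$mutant_id, sim$records$pos)
  ord_rc <- order(rec_rc$mutant_id, -rec_rc$pos)
  expect_equal(ann_rc$region[ord_rc], ann$region[ord])
  expect_equal(ann_rc$ref_aa[ord_rc], ann$ref_aa[ord])
  expect_equal(ann_rc$alt_aa[ord_rc], ann$alt_aa[ord])
})

test_that("nonsynonymous gene list deduplicates and counts calls", {
  calls <- tibble::tibble(
    region = c("exon_nonsynonymous", "exon_nonsynonymous",
               "exon_synonymous", "intron"),
    gene_id = c("g1", "g1", "g2", "g3"))
  gl <- nonsynonymous_gene_list(calls)
  expect_equal(gl$gene_id, "g1")
  expect_equal(gl$n_nonsynonymous, 2L)
  expect_equal(nrow(nonsynonymous_gene_list(
    tibble::tibble(region = "intron", gene_id = "g1"))), 0L)
})
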