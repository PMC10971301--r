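test_that("extract_context reads flanks and collapses G/T-centred sites", {
  g <- tiny_genome(c(c1 = "TTAGG"))  # site at pos 3 has 5'=A? no: T T A G G
  rec <- make_records("c1", 3, "A", "G")
  ctx <- extract_context(rec, g)
  expect_equal(ctx$five_prime, "T")
  expect_equal(ctx$three_prime, "G")
  expect_equal(ctx$trinucleotide, "TAG")

  # G-centred site: local triplet CGT reverse-complements to ACG
  g2 <- tiny_genome(c(c1 = "ACGTA"))
  rec2 <- make_records("c1", 3, "G", "A")
  ctx2 <- extract_context(rec2, g2)
  expect_equal(ctx2$centre, "C")
  expect_equal(ctx2$five_prime, "A")
  expect_equal(ctx2$three_prime, "G")
  expect_equal(ctx2$trinucleotide, "ACG")
})

test_that("contig-edge sites are flagged and excluded with a count", {
  g <- tiny_genome(c(c1 = "ACGT"))
  rec <- make_records("c1", c(1, 2, 4), c("A", "C", "T"), c("G", "T", "A"))
  ctx <- suppressMessages(extract_context(rec, g))
  expect_equal(attr(ctx, "n_edge"), 2L)
  expect_equal(ctx$at_edge, c(TRUE, FALSE, TRUE))
  expect_true(is.na(ctx$trinucleotide[1]))
})

test_that("genome motif counts match the brute-force both-strand oracle", {
  # spec worked example: TATA has 4 both-strand TA occurrences
  g <- tiny_genome(c(c1 = "TATA"))
  n <- genome_motif_counts(g, "A", "5prime")
  expect_equal(n$N[n$flank_base == "T"], 4)

  expect_true(all(genome_motif_counts(tiny_genome(c(c1 = "CCCC")),
                                      "A", "5prime")$N == 0))

  # random small genomes, all 16 (centre, side, base) motifs
  set.seed(7)
  for (rep in 1:5) {
    seqs <- vapply(1:2, function(i) {
      paste(sample(c("A", "C", "G", "T"), sample(50:1000, 1),
                   replace = TRUE), collapse = "")
    }, character(1))
    g <- tiny_genome(seqs)
    for (ce in c("A", "C")) for (sd in c("5prime", "3prime")) {
      got <- genome_motif_counts(g, ce, sd)
      want <- vapply(got$motif, function(m) {
        brute_motif_count(as.character(g), m)
      }, numeric(1))
      expect_equal(got$N, unname(want))
    }
  }
})

test_that("motif counts are invariant under reverse-complementing the genome", {
  set.seed(11)
  s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  g <- tiny_genome(c(c1 = s))
  g_rc <- tiny_genome(c(c1 = rc_oracle(s)))
  for (ce in c("A", "C")) for (sd in c("5prime", "3prime")) {
    expect_equal(genome_motif_counts(g, ce, sd)$N,
                 genome_motif_counts(g_rc, ce, sd)$N)
  }
})

test_that("standardized frequency is n/N x 1e6 and linear in n", {
  expect_equal(standardized_frequency(5, 1e6), 5)
  expect_equal(standardized_frequency(0, 10), 0)
  expect_equal(standardized_frequency(352, 5000) /
                 standardized_frequency(176, 5000), 2)
  expect_warning(out <- standardized_frequency(1, 0), "NA")
  expect_true(is.na(out))
})

test_that("context frequency table ties out against the spectrum", {
  set.seed(3)
  g <- sim_genome(c(c1 = 20000L), gc = 0.5, seed = 31)
  sim <- sim_mutants(g, n_mutants = 3, snvs_per_mutant = 60, seed = 32)
  tbl <- suppressMessages(context_frequency_table(g, sim$records))
  spec <- spectrum_table(sim$records)
  ctx <- suppressMessages(extract_context(sim$records, g))
  n_edge <- attr(ctx, "n_edge")
  # per class, summing mutated-motif n over the four flank bases on one
  # side recovers the class count minus edge-excluded sites
  per_class <- tbl %>%
    dplyr::filter(side == "5prime") %>%
    dplyr::group_by(class) %>%
    dplyr::summarise(n = sum(n))
  cls_map <- c("A→G" = "A:T→G:C", "A→T" = "A:T→T:A", "A→C" = "A:T→C:G",
               "C→T" = "G:C→A:T", "C→A" = "G:C→T:A", "C→G" = "G:C→C:G")
  edge_by_class <- table(ctx$cls[ctx$at_edge])
  for (i in seq_len(nrow(per_class))) {
    cls <- per_class$class[i]
    want <- spec$count[spec$class == cls_map[[cls]]] -
      (if (cls %in% names(edge_by_class)) edge_by_class[[cls]] else 0L)
    expect_equal(per_class$n[i], as.integer(want))
  }
})

test_that("single record yields exactly one nonzero trinucleotide cell", {
  g <- tiny_genome(c(c1 = "ATCGA"))
  rec <- make_records("c1", 3, "C", "T")  # context TCG
  tri <- suppressWarnings(trinucleotide_counts(g, rec)) # tiny genome: some N = 0
  nz <- tri[tri$n > 0, ]
  expect_equal(nrow(nz), 1L)
  expect_equal(nz$trinucleotide, "TCG")
  expect_equal(nz$class, "C→T")
  expect_equal(nz$n, 1L)
})

test_that("planted 5'-flank bias is recovered in frequency order", {
  g <- sim_genome(c(c1 = 60000L), gc = 0.5, seed = 41)
  sim <- sim_mutants(g, n_mutants = 10, snvs_per_mutant = 80,
                     class_weights = c("G:C→A:T" = 0, "A:T→G:C" = 1,
                                       "A:T→T:A" = 0, "G:C→T:A" = 0,
                                       "A:T→C:G" = 0, "G:C→C:G" = 0),
                     context_weights = c(T = 4, A = 3, C = 2, G = 1),
                     seed = 42)
  tbl <- suppressMessages(context_frequency_table(g, sim$records))
  f <- tbl %>%
    dplyr::filter(side == "5prime", class == "A→G") %>%
    dplyr::arrange(match(flank_base, c("T", "A", "C", "G")))
  expect_equal(f$flank_base[order(-f$frequency)], c("T", "A", "C", "G"))
})
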