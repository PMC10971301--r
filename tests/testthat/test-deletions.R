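test_that("kmer_set canonicalizes windows and drops N-containing ones", {
  ks <- kmer_set("ACGTACGT", k = 5)
  # brute-force oracle: 4 windows, canonical set {ACGTA, CGTAC}
  expect_equal(ks$kmers, brute_kmer_set("ACGTACGT", 5))
  expect_equal(length(ks$kmers), 2L)

  expect_warning(empty <- kmer_set(strrep("N", 40), k = 11), "no k-mers")
  expect_equal(length(empty$kmers), 0L)

  # strand independence by canonicalization
  set.seed(23)
  s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  expect_equal(kmer_set(s, 11)$kmers, kmer_set(rc_oracle(s), 11)$kmers)

  # multiplicity floor
  expect_equal(length(kmer_set(c("ACGTACGTACG", "ACGTACGTACG"), 11,
                               min_count = 2)$kmers), 1L)
  expect_equal(length(kmer_set("ACGTACGTACG", 11, min_count = 2)$kmers), 0L)
})

test_that("exclusive_kmers is plain set difference with k checked", {
  a <- kmer_set("ACGTACGTACGAA", 11)
  expect_equal(length(exclusive_kmers(a, a)$kmers), 0L)
  b <- kmer_set(strrep("GGTT", 10), 11)
  expect_equal(exclusive_kmers(a, b)$kmers, a$kmers)
  expect_error(exclusive_kmers(a, kmer_set("ACGTACGTACGAA", 13)),
               "k mismatch")
})

test_that("an excised fragment leaves ~length+k-1 exclusive k-mers", {
  g <- sim_genome(c(c1 = 10000L), gc = 0.5, seed = 81)
  s <- as.character(g[[1]])
  mut <- paste0(substr(s, 1, 4999), substr(s, 5300, 10000)) # 300 bp out
  wt <- kmer_set(g, 31)
  ex <- exclusive_kmers(wt, kmer_set(mut, 31))
  # every k-mer overlapping the excision is exclusive unless it recurs
  expect_lte(length(ex$kmers), 300 + 31 - 1)
  expect_gt(length(ex$kmers), 300 - 31) # nearly all unique at 10 kb
  calls <- call_deletions(ex, g)
  expect_equal(nrow(calls), 1L)
  expect_lte(abs(calls$start - 5000), 30)
  expect_lte(abs(calls$end - 5299), 30)
  expect_lte(abs(calls$length - 300), 30)
})

test_that("deletions below the length floor are rejected", {
  g <- sim_genome(c(c1 = 10000L), gc = 0.5, seed = 82)
  s <- as.character(g[[1]])
  mut <- paste0(substr(s, 1, 4999), substr(s, 5150, 10000)) # 150 bp out
  ex <- exclusive_kmers(kmer_set(g, 31), kmer_set(mut, 31))
  expect_gt(length(ex$kmers), 0L)
  expect_equal(nrow(call_deletions(ex, g)), 0L)
  expect_equal(nrow(call_deletions(
    structure(list(k = 31L, kmers = character()), class = "kmer_set"), g)),
    0L)
})

test_that("the read-based screen recovers planted deletions precisely", {
  g <- sim_genome(c(c1 = 50000L), gc = 0.48, seed = 83)
  dels <- tibble::tibble(contig = "c1",
                         start = c(8000L, 30000L),
                         length = c(720L, 290L))
  sim <- sim_mutants(g, n_mutants = 2, snvs_per_mutant = 30,
                     deletions = dels, seed = 84)
  k <- 31L
  truth <- sim$truth$deletions
  for (i in seq_len(nrow(truth))) {
    mid <- truth$mutant_id[i]
    reads <- sim_reads(sim$mutant_genomes[[mid]], coverage = 30,
                       read_len = 100L, error_rate = 0, seed = 85 + i)
    calls <- deletion_screen(g, reads, k = k)
    expect_equal(nrow(calls), 1L)
    expect_lte(abs(calls$start - truth$start[i]), k - 1)
    expect_lte(abs(calls$end - truth$end[i]), k - 1)
    expect_lte(abs(calls$length - truth$length[i]), k - 1)
    # no call overlaps unmutated sequence beyond breakpoint slack
    expect_gte(calls$start, truth$start[i] - (k - 1))
    expect_lte(calls$end, truth$end[i] + (k - 1))
    # determinism
    calls2 <- deletion_screen(g, reads, k = k)
    expect_identical(as.data.frame(calls), as.data.frame(calls2))
  }
})

test_that("deletion calls are disjoint, sorted, and export as BED", {
  g <- sim_genome(c(c1 = 30000L), gc = 0.5, seed = 86)
  s <- as.character(g[[1]])
  # two excisions in one mutant assembly
  mut <- paste0(substr(s, 1, 4999), substr(s, 5250, 19999),
                substr(s, 20300, 30000))
  calls <- deletion_screen(g, mut, k = 31, mutant_min_count = 1)
  expect_equal(nrow(calls), 2L)
  expect_true(all(diff(calls$start) > 0))
  expect_true(all(calls$end[-nrow(calls)] < calls$start[-1]))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_deletions_bed(calls, bed)
  rows <- strsplit(readLines(bed), "\t")
  expect_equal(as.integer(rows[[1]][2]), calls$start[1] - 1L)
  expect_equal(as.integer(rows[[1]][3]), calls$end[1])
})
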