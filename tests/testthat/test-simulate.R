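test_that("simulated genomes hit the target GC and reproduce by seed", {
  g <- sim_genome(c(tig1 = 100000L), gc = 0.48, seed = 1)
  freq <- Biostrings::alphabetFrequency(g)[1, c("A", "C", "G", "T")]
  gc <- sum(freq[c("C", "G")]) / sum(freq)
  expect_lt(abs(gc - 0.48), 0.01) # binomial concentration at 100 kb

  g2 <- sim_genome(c(tig1 = 100000L), gc = 0.48, seed = 1)
  expect_identical(as.character(g), as.character(g2))

  at_only <- sim_genome(c(tig1 = 500L), gc = 0, seed = 2)
  expect_equal(sum(Biostrings::alphabetFrequency(at_only)[1, c("C", "G")]), 0)

  expect_error(sim_genome(c(tig1 = 0L), gc = 0.5, seed = 3))
})

test_that("simulated mutants realise their planted classes exactly", {
  g <- sim_genome(c(c1 = 30000L), gc = 0.5, seed = 4)
  sim <- sim_mutants(g, n_mutants = 4, snvs_per_mutant = 25, seed = 5)
  expect_lte(nrow(sim$records), 100L) # adjacency pruning may drop a few
  expect_gte(nrow(sim$records), 95L)
  # end-to-end identity: observed collapsed class == planted class
  obs <- collapse_substitution(sim$records$ref, sim$records$alt)$cls_paired
  truth <- sim$truth$spectrum
  key <- paste(sim$records$mutant_id, sim$records$contig, sim$records$pos)
  tkey <- paste(truth$mutant_id, truth$contig, truth$pos)
  expect_equal(obs, truth$cls_true[match(key, tkey)])
  # every record's ref base matches the genome (valid by construction)
  expect_silent(validate_records(sim$records, g))
})

test_that("zero SNVs produce empty outputs", {
  g <- sim_genome(c(c1 = 5000L), gc = 0.5, seed = 6)
  sim <- sim_mutants(g, n_mutants = 2, snvs_per_mutant = 0, seed = 7)
  expect_equal(nrow(sim$records), 0L)
  expect_equal(nrow(sim$truth$spectrum), 0L)
})

test_that("planted gene models are clean CDS-only models", {
  g <- sim_genome(c(c1 = 100000L), gc = 0.5, seed = 8)
  pl <- plant_gene_models(g, 10, 300L, seed = 9)
  expect_equal(nrow(pl$models), 10L)
  # non-overlapping
  m <- dplyr::arrange(pl$models, start)
  expect_true(all(m$start[-1] > m$end[-nrow(m)]))
  # translatable: ATG start, no internal stop, terminal stop
  for (i in seq_len(nrow(m))) {
    s <- substr(as.character(pl$genome[[m$contig[i]]]), m$start[i], m$end[i])
    if (m$strand[i] == "-") s <- rc_oracle(s)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
  expect_equal(nrow(plant_gene_models(g, 0, seed = 10)$models), 0L)
  expect_error(plant_gene_models(g, 1e6, 300L, seed = 11), "fit")
})

test_that("a site 100 bp upstream of a planted + strand ATG is promoter", {
  g <- sim_genome(c(c1 = 50000L), gc = 0.5, seed = 12)
  pl <- plant_gene_models(g, 8, 300L, seed = 13)
  gp <- pl$models[pl$models$strand == "+", ][1, ]
  p <- gp$start - 100L
  ref <- substr(as.character(pl$genome[[gp$contig]]), p, p)
  rec <- make_records(gp$contig, p, ref, setdiff(c("A", "C", "G", "T"), ref)[1])
  expect_equal(annotate_sites(rec, pl$models, pl$genome)$region,
               "core_promoter")
})

test_that("simulated reads have the right depth and are error-free substrings", {
  g <- sim_genome(c(c1 = 10000L), gc = 0.5, seed = 14)
  reads <- sim_reads(g, coverage = 30, read_len = 100L, error_rate = 0,
                     seed = 15)
  expect_equal(length(reads), 3000L) # 30 * 10000 / 100
  s <- as.character(g[[1]])
  for (r in reads[1:25]) {
    expect_true(grepl(r, s, fixed = TRUE) ||
                  grepl(rc_oracle(r), s, fixed = TRUE))
  }
  expect_error(sim_reads(g, coverage = 0, seed = 16))
  expect_error(sim_reads(g, coverage = 5, read_len = 99999L, seed = 17),
               "shortest contig")
})

test_that("bundle generation is reproducible byte for byte", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  args <- list(contig_lengths = c(tig1 = 20000L), n_genes = 5L,
               n_mutants = 3L, snvs_per_mutant = 10L,
               tandem_classes = c(double_transition = 2L),
               reads_for = "mut001", coverage = 5, seed = 18L)
  b1 <- do.call(sim_bundle, c(list(dir = d1), args))
  b2 <- do.call(sim_bundle, c(list(dir = d2), args))
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  # the bundle feeds straight back into the pipeline
  g <- read_genome(file.path(d1, "genome.fa"))
  rec <- suppressMessages(read_snv_dir(file.path(d1, "mutants")))
  expect_equal(as.data.frame(rec[order(rec$mutant_id, rec$contig, rec$pos), ]),
               as.data.frame(b1$records[order(b1$records$mutant_id,
                                              b1$records$contig,
                                              b1$records$pos), ]),
               ignore_attr = TRUE)
  expect_silent(validate_records(rec, g))
  td <- find_tandems(rec)
  expect_equal(nrow(td), 2L)
})
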