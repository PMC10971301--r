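# Shared fixture builders and independent oracles.
# Oracles deliberately avoid the package's own code paths (manual string
# handling instead of Biostrings, loops instead of vectorised counts).

make_records <- function(contig, pos, ref, alt, mutant_id = "m1") {
  tibble::tibble(mutant_id = mutant_id, contig = contig,
                 pos = as.integer(pos), ref = ref, alt = alt)
}

# Records realising exact per-class counts of the six paired classes, on
# a dummy contig with distinct positions. Uses one fixed (ref, alt)
# realisation per class.
records_with_class_counts <- function(counts) {
  # paired class -> a concrete (ref, alt) realisation
  realis <- list("G:C→A:T" = c("C", "T"), "A:T→G:C" = c("A", "G"),
                 "A:T→T:A" = c("T", "A"), "G:C→T:A" = c("G", "T"),
                 "A:T→C:G" = c("A", "C"), "G:C→C:G" = c("C", "G"))
  stopifnot(all(names(counts) %in% names(realis)))
  ref <- unlist(mapply(function(cls, n) rep(realis[[cls]][1], n),
                       names(counts), counts))
  alt <- unlist(mapply(function(cls, n) rep(realis[[cls]][2], n),
                       names(counts), counts))
  make_records("c1", seq(1, by = 2, length.out = length(ref)), ref, alt)
}

TABLE_CLASS_COUNTS <- c("G:C→A:T" = 2239L, "A:T→G:C" = 651L,
                        "A:T→T:A" = 394L, "G:C→T:A" = 221L,
                        "A:T→C:G" = 135L, "G:C→C:G" = 67L)

# Manual reverse complement, independent of Biostrings.
rc_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Brute-force both-strand motif count: loop over every window of the
# forward sequence and of its reverse complement.
brute_motif_count <- function(seqs, motif) {
  scan1 <- function(s, m) {
    k <- nchar(m); L <- nchar(s)
    if (L < k) return(0L)
    sum(vapply(seq_len(L - k + 1),
               function(i) substr(s, i, i + k - 1) == m, logical(1)))
  }
  sum(vapply(seqs, function(s) {
    scan1(s, motif) + scan1(rc_oracle(s), motif)
  }, numeric(1)))
}

# Brute-force canonical k-mer set of a single sequence.
brute_kmer_set <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character())
  win <- vapply(seq_len(L - k + 1), function(i) substr(s, i, i + k - 1),
                character(1))
  win <- win[!grepl("N", win, fixed = TRUE)]
  sort(unique(vapply(win, function(w) min(w, rc_oracle(w)), character(1),
                     USE.NAMES = FALSE)))
}

# Expected-count summation form of the Pearson statistic, as an
# independent check on the closed form.
chisq_expected_form <- function(m) {
  m <- matrix(as.numeric(m), 2, 2)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Small deterministic genome useful across files.
tiny_genome <- function(seqs) {
  g <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(g) <- paste0("c", seq_along(seqs))
  else names(g) <- names(seqs)
  g
}
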