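# All overlapping k-windows of a character vector of sequences.
kmerize <- function(seqs, k) {
  L <- nchar(seqs)
  seqs <- seqs[L >= k]
  L <- L[L >= k]
  if (length(seqs) == 0) return(character())
  nw <- L - k + 1L
  starts <- sequence(nw)
  substring(rep.int(seqs, nw), starts, starts + k - 1L)
}

# Canonical form: lexicographic min of a k-mer and its reverse complement.
canonicalize <- function(kmers) {
  if (length(kmers) == 0) return(kmers)
  u <- unique(kmers)
  rc <- revcomp(u)
  can <- pmin(u, rc)
  can[match(kmers, u)]
}

#' Build a canonical k-mer set
#'
#' Extracts every k-window without N from the input sequences,
#' canonicalizes (lexicographic min of k-mer and reverse complement), and
#' keeps k-mers seen at least `min_count` times. For sequencing reads a
#' `min_count` of 2 suppresses error k-mers; for an assembled genome use 1.
#'
#' @param seqs A `DNAStringSet`, or character vector of sequences (reads or
#'   contigs).
#' @param k Odd k-mer size (3-63; 31 is the working default, sizes below
#'   ~11 are only useful on toy sequences).
#' @param min_count Minimum multiplicity to retain a k-mer.
#' @return An object of class `kmer_set`: list with `k` and the sorted
#'   unique canonical `kmers`.
#' @export
kmer_set <- function(seqs, k = 31L, min_count = 1L) {
  stopifnot(k %% 2 == 1, k >= 3, k <= 63)
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  km <- kmerize(toupper(seqs), k)
  km <- km[!grepl("N", km, fixed = TRUE)]
  if (length(km) == 0) {
    warning("no k-mers extracted (k larger than every sequence?)", call. = FALSE)
    return(structure(list(k = as.integer(k), kmers = character()),
                     class = "kmer_set"))
  }
  km <- canonicalize(km)
  if (min_count > 1L) {
    tab <- table(km)
    km <- names(tab)[tab >= min_count]
  } else {
    km <- unique(km)
  }
  structure(list(k = as.integer(k), kmers = sort(km)), class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat("canonical kmer_set: k =", x$k, ",", length(x$kmers), "k-mers\n")
  invisible(x)
}

#' Set difference of two k-mer sets
#'
#' K-mers present in the wild-type set but absent from the mutant set —
#' the signature of sequence deleted in the mutant.
#'
#' @param wt,mut `kmer_set` objects with equal `k`.
#' @return A `kmer_set` containing `wt - mut`.
#' @export
exclusive_kmers <- function(wt, mut) {
  stopifnot(inherits(wt, "kmer_set"), inherits(mut, "kmer_set"))
  if (wt$k != mut$k) stop("k mismatch: ", wt$k, " vs ", mut$k, call. = FALSE)
  structure(list(k = wt$k, kmers = setdiff(wt$kmers, mut$kmers)),
            class = "kmer_set")
}

# Unique anchor positions of canonical genome k-mers: tibble
# (kmer, contig, start) restricted to k-mers occurring exactly once in the
# whole genome.
genome_kmer_anchors <- function(genome, k) {
  per_contig <- purrr::map2_dfr(names(genome), as.character(genome),
    function(ct, seq_str) {
      km <- kmerize(seq_str, k)
      if (length(km) == 0) return(tibble::tibble(
        kmer = character(), contig = character(), start = integer()))
      tibble::tibble(kmer = canonicalize(km), contig = ct,
                     start = seq_along(km))
    })
  per_contig <- per_contig[!grepl("N", per_contig$kmer, fixed = TRUE), ]
  dup <- unique(per_contig$kmer[duplicated(per_contig$kmer)])
  per_contig[!(per_contig$kmer %in% dup), ]
}

#' Call deletions from exclusive k-mers
#'
#' Anchors each wild-type-exclusive k-mer at its unique reference position
#' (multi-mapping k-mers dropped) and merges anchors whose start-position
#' gaps are at most `max_gap` into candidate intervals. A deletion
#' spanning reference bases s..e turns every k-mer starting in
#' s-k+1 .. e exclusive, so the deletion interval is estimated by
#' trimming k-1 bases from the left of the anchor span: start =
#' first anchor + k - 1, end = last anchor. Anchors lost to repeats
#' erode the interval inward, so each breakpoint carries at most k - 1 bp
#' of error. Intervals shorter than `min_length` are discarded (isolated
#' SNVs produce anchor runs that collapse to ~1 bp and vanish here).
#'
#' @param excl `kmer_set` of wild-type-exclusive k-mers.
#' @param genome `DNAStringSet` reference (wild type).
#' @param min_length Minimum reported interval length in bp (default 200,
#'   the screen's detection floor).
#' @param max_gap Maximum anchor start-gap bridged within one interval
#'   (default `k`, covering anchors lost to repeats).
#' @return A tibble of class `uv_deletions`: `contig`, `start`, `end`
#'   (1-based closed), `length`, `support` (anchor count), `density`
#'   (support over possible anchor starts in the interval), sorted and
#'   disjoint.
#' @export
call_deletions <- function(excl, genome, min_length = 200L, max_gap = NULL) {
  stopifnot(inherits(excl, "kmer_set"))
  k <- excl$k
  if (is.null(max_gap)) max_gap <- k
  empty <- tibble::tibble(contig = character(), start = integer(),
                          end = integer(), length = integer(),
                          support = integer(), density = numeric())
  class(empty) <- c("uv_deletions", class(empty))
  if (length(excl$kmers) == 0) return(empty)
  anchors <- genome_kmer_anchors(genome, k)
  hits <- anchors[anchors$kmer %in% excl$kmers, ]
  if (nrow(hits) == 0) return(empty)
  out <- hits %>%
    dplyr::arrange(.data$contig, .data$start) %>%
    dplyr::group_by(.data$contig) %>%
    dplyr::mutate(cluster = cumsum(c(1L, diff(.data$start) > max_gap))) %>%
    dplyr::group_by(.data$contig, .data$cluster) %>%
    dplyr::summarise(
      first_anchor = min(.data$start),
      last_anchor = max(.data$start),
      support = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::mutate(start = .data$first_anchor + k - 1L,
                  end = .data$last_anchor,
                  length = .data$end - .data$start + 1L,
                  density = .data$support /
                    (.data$last_anchor - .data$first_anchor + 1L)) %>%
    dplyr::filter(.data$length >= min_length) %>%
    dplyr::select("contig", "start", "end", "length", "support", "density") %>%
    dplyr::arrange(.data$contig, .data$start)
  class(out) <- c("uv_deletions", class(out))
  out
}

#' Write deletion calls as BED
#'
#' Converts the internal 1-based closed intervals to BED's 0-based
#' half-open convention.
#'
#' @param calls Output of [call_deletions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deletions_bed <- function(calls, path) {
  bed <- tibble::as_tibble(calls) %>%
    dplyr::transmute(.data$contig, start = .data$start - 1L, end = .data$end,
                     name = sprintf("del_%dbp", .data$length),
                     score = .data$support)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Run the whole deletion screen
#'
#' Convenience wrapper: wild-type k-mers from the reference assembly
#' (`min_count` 1), mutant k-mers from reads (`min_count` 2), set
#' difference, anchoring and interval calling.
#'
#' @param genome `DNAStringSet` wild-type reference.
#' @param mutant_seqs Mutant reads or assembly (`DNAStringSet`/character).
#' @param k K-mer size (odd, default 31).
#' @param min_length Minimum deletion length (default 200).
#' @param max_gap Anchor merge gap (default `k`).
#' @param mutant_min_count Multiplicity floor for mutant k-mers (default 2,
#'   use 1 for assembled input).
#' @return A `uv_deletions` tibble, see [call_deletions()].
#' @export
deletion_screen <- function(genome, mutant_seqs, k = 31L, min_length = 200L,
                            max_gap = NULL, mutant_min_count = 2L) {
  wt <- kmer_set(genome, k, min_count = 1L)
  mut <- kmer_set(mutant_seqs, k, min_count = mutant_min_count)
  call_deletions(exclusive_kmers(wt, mut), genome,
                 min_length = min_length, max_gap = max_gap)
}
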