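#' Extract strand-collapsed trinucleotide contexts for mutation sites
#'
#' For each record, reads the genomic base on each side of the mutated
#' position. Sites whose reference base is G or T are reverse-complemented
#' so the centre is always A or C; the flanks swap sides accordingly.
#' Contig-edge sites (no flank on one side) are flagged and carry `NA`
#' context; they are excluded from motif tallies downstream.
#'
#' @param records Records tibble.
#' @param genome `DNAStringSet` reference.
#' @return The records tibble with added columns `centre`, `cls`,
#'   `cls_paired`, `five_prime`, `three_prime`, `trinucleotide` and
#'   `at_edge`. The number of edge-excluded sites is attached as attribute
#'   `n_edge`.
#' @export
extract_context <- function(records, genome) {
  records <- validate_records(records, genome)
  col <- collapse_records(records)
  len <- Biostrings::width(genome)[match(col$contig, names(genome))]
  at_edge <- col$pos == 1L | col$pos == len
  up <- rep(NA_character_, nrow(col))
  down <- up
  inb <- !at_edge
  up[inb] <- genome_base_at(genome, col$contig[inb], col$pos[inb] - 1L)
  down[inb] <- genome_base_at(genome, col$contig[inb], col$pos[inb] + 1L)
  # collapsed orientation: flipping the strand swaps and complements flanks
  five_prime <- ifelse(col$strand_flipped, complement_bases(down), up)
  three_prime <- ifelse(col$strand_flipped, complement_bases(up), down)
  out <- col %>%
    dplyr::mutate(
      five_prime = five_prime,
      three_prime = three_prime,
      trinucleotide = ifelse(at_edge, NA_character_,
                             paste0(five_prime, .data$centre, three_prime)),
      at_edge = at_edge
    )
  n_edge <- sum(at_edge)
  if (n_edge > 0) message("extract_context: ", n_edge, " contig-edge site(s) excluded from motif tallies")
  attr(out, "n_edge") <- n_edge
  out
}

# Occurrences of a motif counted on both strands of the genome: forward
# scan of the motif plus forward scan of its reverse complement
# (overlapping occurrences all count).
count_motif_both_strands <- function(genome, motif) {
  fwd <- sum(Biostrings::vcountPattern(motif, genome))
  rev <- sum(Biostrings::vcountPattern(revcomp(motif), genome))
  fwd + rev
}

#' Genome-wide flanking-dinucleotide counts
#'
#' For a centre base (A or C) and a flank side, counts the four
#' dinucleotide motifs (`5'-XA-3'` etc. for the 5' side, `5'-AX-3'` for the
#' 3' side) across the genome. Because mutations are strand-collapsed,
#' occurrences are counted on both strands by default.
#'
#' @param genome `DNAStringSet`.
#' @param centre `"A"` or `"C"`.
#' @param side `"5prime"` or `"3prime"`: which flank varies.
#' @param both_strands Count the reverse strand too (default `TRUE`,
#'   matching the strand-collapsed mutation universe).
#' @return A tibble: `side`, `flank_base`, `motif`, `N`.
#' @export
genome_motif_counts <- function(genome, centre = c("A", "C"),
                                side = c("5prime", "3prime"),
                                both_strands = TRUE) {
  centre <- match.arg(centre); side <- match.arg(side)
  motifs <- if (side == "5prime") paste0(BASES, centre) else paste0(centre, BASES)
  N <- vapply(motifs, function(m) {
    if (both_strands) count_motif_both_strands(genome, m)
    else sum(Biostrings::vcountPattern(m, genome))
  }, numeric(1))
  tibble::tibble(side = side, flank_base = BASES, motif = motifs, N = unname(N))
}

#' Standardized mutation frequency
#'
#' The mutated-motif count `n` divided by the genome-wide motif count `N`,
#' scaled by 10^6.
#'
#' @param n Mutated occurrences (vectorised).
#' @param N Genome occurrences.
#' @return `n / N * 1e6`; `NA` with a warning where `N` is zero.
#' @export
standardized_frequency <- function(n, N) {
  out <- ifelse(N > 0, n / N * 1e6, NA_real_)
  if (any(N == 0)) warning("standardized_frequency: N = 0 yields NA", call. = FALSE)
  out
}

#' Flanking-base standardized mutation frequency table
#'
#' One standardized frequency per (flank side, flank base, substitution
#' class): the number of (non-edge, strand-collapsed) mutated sites with
#' that flank, divided by the genome-wide count of the corresponding
#' dinucleotide, times 10^6.
#'
#' @param genome `DNAStringSet`.
#' @param records Records tibble.
#' @param both_strands Passed to [genome_motif_counts()].
#' @return A tibble: `side`, `flank_base`, `class` (e.g. `"A→G"`), `n`,
#'   `N`, `frequency`.
#' @export
context_frequency_table <- function(genome, records, both_strands = TRUE) {
  ctx <- extract_context(records, genome) %>% dplyr::filter(!.data$at_edge)
  grid <- tidyr::expand_grid(
    side = c("5prime", "3prime"),
    flank_base = BASES,
    cls = c("A→G", "A→T", "A→C", "C→T", "C→A", "C→G")
  ) %>%
    dplyr::mutate(centre = substr(.data$cls, 1, 1))
  n_tbl <- dplyr::bind_rows(
    ctx %>% dplyr::count(flank_base = .data$five_prime, .data$cls) %>%
      dplyr::mutate(side = "5prime"),
    ctx %>% dplyr::count(flank_base = .data$three_prime, .data$cls) %>%
      dplyr::mutate(side = "3prime")
  )
  N_tbl <- purrr::map_dfr(c("A", "C"), function(ce) {
    dplyr::bind_rows(
      genome_motif_counts(genome, ce, "5prime", both_strands),
      genome_motif_counts(genome, ce, "3prime", both_strands)
    ) %>% dplyr::mutate(centre = ce)
  })
  grid %>%
    dplyr::left_join(n_tbl, by = c("side", "flank_base", "cls")) %>%
    dplyr::left_join(N_tbl, by = c("side", "flank_base", "centre")) %>%
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      frequency = standardized_frequency(.data$n, .data$N)
    ) %>%
    dplyr::select("side", "flank_base", class = "cls", "motif", "n", "N",
                  "frequency") %>%
    dplyr::arrange(dplyr::desc(.data$side), .data$flank_base, .data$class)
}

#' Per-trinucleotide mutated-site counts
#'
#' The 32-row table (16 A-centred + 16 C-centred trinucleotides) of mutated
#' occurrences per substitution class, with genome-wide trinucleotide
#' counts on both strands.
#'
#' @param genome `DNAStringSet`.
#' @param records Records tibble.
#' @param both_strands Count genome motifs on both strands (default `TRUE`).
#' @return A tibble: `trinucleotide`, `class`, `n`, `N`, `frequency`, plus
#'   a per-trinucleotide `n_total` across classes.
#' @export
trinucleotide_counts <- function(genome, records, both_strands = TRUE) {
  ctx <- extract_context(records, genome) %>% dplyr::filter(!.data$at_edge)
  grid <- tidyr::expand_grid(five = BASES, centre = c("A", "C"), three = BASES) %>%
    dplyr::mutate(trinucleotide = paste0(.data$five, .data$centre, .data$three))
  N <- vapply(grid$trinucleotide, function(m) {
    if (both_strands) count_motif_both_strands(genome, m)
    else sum(Biostrings::vcountPattern(m, genome))
  }, numeric(1))
  grid$N <- unname(N)
  counts <- ctx %>% dplyr::count(.data$trinucleotide, .data$cls)
  grid %>%
    dplyr::left_join(counts, by = "trinucleotide") %>%
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  class = .data$cls) %>%
    dplyr::group_by(.data$trinucleotide) %>%
    dplyr::mutate(n_total = sum(.data$n)) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(frequency = standardized_frequency(.data$n, .data$N)) %>%
    dplyr::select("trinucleotide", "class", "n", "n_total", "N", "frequency")
}
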