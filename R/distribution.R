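#' Per-contig mutation counts and average spacing
#'
#' Every genome contig appears, including those with zero sites. Average
#' spacing is contig length divided by the number of mutated sites,
#' rounded to the nearest integer; `NA` for empty contigs.
#'
#' @param records Records tibble.
#' @param genome `DNAStringSet` reference, or a data frame with columns
#'   `contig` and `length` (e.g. from a FASTA index).
#' @return A tibble: `contig`, `n_sites`, `length`, `avg_spacing`.
#' @export
contig_summary <- function(records, genome) {
  assert_records(records)
  lens <- as_genome_lengths(genome)
  unknown <- setdiff(unique(records$contig), lens$contig)
  if (length(unknown) > 0) {
    stop("record(s) on unknown contig(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  lens %>%
    dplyr::left_join(dplyr::count(records, .data$contig, name = "n_sites"),
                     by = "contig") %>%
    dplyr::mutate(
      n_sites = dplyr::coalesce(.data$n_sites, 0L),
      avg_spacing = ifelse(.data$n_sites > 0,
                           round(.data$length / .data$n_sites), NA_real_)
    ) %>%
    dplyr::select("contig", "n_sites", "length", "avg_spacing")
}

#' Ordered per-site position track
#'
#' @param records Records tibble.
#' @return A tibble `(contig, pos, mutant_id)` stably sorted by contig then
#'   position; duplicate (contig, pos) across mutants kept as separate rows.
#' @export
position_track <- function(records) {
  assert_records(records)
  records %>%
    dplyr::select("contig", "pos", "mutant_id") %>%
    dplyr::arrange(.data$contig, .data$pos)
}

#' Export a position track as BED
#'
#' BED intervals are 0-based half-open; internal coordinates are 1-based
#' closed, so each site becomes `(pos - 1, pos)`.
#'
#' @param track Output of [position_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_bed <- function(track, path) {
  bed <- track %>%
    dplyr::transmute(.data$contig, start = .data$pos - 1L, end = .data$pos,
                     name = .data$mutant_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Chi-square uniformity diagnostic for mutation placement
#'
#' Tiles each contig into bins of `bin_size` bp (the last, partial bin is
#' kept and length-weighted) and tests per-bin site counts against a
#' length-proportional expectation with a Pearson goodness-of-fit
#' statistic.
#'
#' @param records Records tibble.
#' @param genome `DNAStringSet` reference, or a data frame with columns
#'   `contig` and `length`.
#' @param bin_size Bin width in bp (> 0).
#' @return An object of class `uv_uniformity` with elements `statistic`,
#'   `df`, `p.value`, `n_bins`, `n_sites`; see [tidy.uv_uniformity()].
#' @export
uniformity_test <- function(records, genome, bin_size = 10000) {
  stopifnot(bin_size > 0)
  assert_records(records)
  lens <- as_genome_lengths(genome)
  if (length(setdiff(unique(records$contig), lens$contig)) > 0) {
    stop("record(s) on unknown contig(s)", call. = FALSE)
  }
  bins <- purrr::pmap_dfr(lens, function(contig, length) {
    starts <- seq(1L, length, by = bin_size)
    tibble::tibble(contig = contig, bin_start = starts,
                   bin_end = pmin(starts + bin_size - 1L, length))
  }) %>%
    dplyr::mutate(bin_len = .data$bin_end - .data$bin_start + 1L)
  if (nrow(bins) < 2) stop("fewer than 2 bins; decrease bin_size", call. = FALSE)
  counts <- vapply(seq_len(nrow(bins)), function(i) {
    sum(records$contig == bins$contig[i] &
          records$pos >= bins$bin_start[i] & records$pos <= bins$bin_end[i])
  }, numeric(1))
  expected <- nrow(records) * bins$bin_len / sum(bins$bin_len)
  stat <- sum((counts - expected)^2 / expected)
  df <- nrow(bins) - 1L
  out <- list(statistic = stat, df = df,
              p.value = stats::pchisq(stat, df, lower.tail = FALSE),
              n_bins = nrow(bins), n_sites = nrow(records),
              bin_size = bin_size)
  class(out) <- "uv_uniformity"
  out
}

#' @export
print.uv_uniformity <- function(x, ...) {
  cat("Pearson goodness-of-fit against length-proportional placement\n")
  cat(sprintf("  X-squared = %.4g, df = %d, p = %.3g (%d sites, %d bins of %g bp)\n",
              x$statistic, x$df, x$p.value, x$n_sites, x$n_bins, x$bin_size))
  invisible(x)
}
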