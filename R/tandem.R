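TANDEM_CLASSES <- c("double_transition", "double_transversion",
                    "transition_3prime", "transition_5prime")

#' Classify a tandem dinucleotide substitution
#'
#' Per-position label: transition iff the ref/alt pair is A/G or C/T.
#' The four-way class combines the labels of the 5' and 3' positions.
#' Motifs are read on the reference forward strand, uncollapsed.
#'
#' @param ref_dinuc,alt_dinuc Two-base reference/alternate strings
#'   (vectorised).
#' @return Character vector: one of `"double_transition"`,
#'   `"double_transversion"`, `"transition_3prime"`, `"transition_5prime"`.
#' @examples
#' classify_tandem("CC", "TT") # double_transition
#' classify_tandem("AC", "TT") # transition_3prime
#' @export
classify_tandem <- function(ref_dinuc, alt_dinuc) {
  r5 <- substr(ref_dinuc, 1, 1); r3 <- substr(ref_dinuc, 2, 2)
  a5 <- substr(alt_dinuc, 1, 1); a3 <- substr(alt_dinuc, 2, 2)
  if (any(r5 == a5) || any(r3 == a3)) {
    stop("both positions of a tandem must differ from the reference",
         call. = FALSE)
  }
  ti5 <- is_transition(r5, a5)
  ti3 <- is_transition(r3, a3)
  dplyr::case_when(
    ti5 & ti3 ~ "double_transition",
    !ti5 & !ti3 ~ "double_transversion",
    !ti5 & ti3 ~ "transition_3prime",
    TRUE ~ "transition_5prime"
  )
}

#' Find tandem mutations within mutants
#'
#' A tandem mutation is a maximal run of exactly two adjacent mutated
#' positions on one contig within one mutant. Runs of three or more
#' adjacent mutated bases are excluded from the four-class tally and
#' returned separately via the `long_runs` attribute.
#'
#' @param records Records tibble.
#' @return A tibble of class `uv_tandems`: `mutant_id`, `contig`, `pos5`,
#'   `ref_dinuc`, `alt_dinuc`, `class`, `bond_change_5prime`. Attribute
#'   `long_runs` holds a tibble of multi-site (>= 3) runs with their
#'   lengths.
#' @export
find_tandems <- function(records) {
  assert_records(records)
  empty <- tibble::tibble(mutant_id = character(), contig = character(),
                          pos5 = integer(), ref_dinuc = character(),
                          alt_dinuc = character(), class = character(),
                          bond_change_5prime = logical())
  if (nrow(records) == 0) {
    attr(empty, "long_runs") <- tibble::tibble(
      mutant_id = character(), contig = character(),
      run_start = integer(), run_length = integer())
    class(empty) <- c("uv_tandems", class(empty))
    return(empty)
  }
  runs <- records %>%
    dplyr::distinct(.data$mutant_id, .data$contig, .data$pos,
                    .keep_all = TRUE) %>%
    dplyr::arrange(.data$mutant_id, .data$contig, .data$pos) %>%
    dplyr::group_by(.data$mutant_id, .data$contig) %>%
    dplyr::mutate(run = cumsum(c(1L, diff(.data$pos) != 1L))) %>%
    dplyr::group_by(.data$mutant_id, .data$contig, .data$run)
  run_info <- runs %>%
    dplyr::summarise(run_start = min(.data$pos), run_length = dplyr::n(),
                     ref_dinuc = paste(.data$ref, collapse = ""),
                     alt_dinuc = paste(.data$alt, collapse = ""),
                     .groups = "drop")
  long_runs <- run_info %>%
    dplyr::filter(.data$run_length >= 3L) %>%
    dplyr::select("mutant_id", "contig", "run_start", "run_length")
  if (nrow(long_runs) > 0) {
    message("find_tandems: ", nrow(long_runs),
            " run(s) of >= 3 adjacent mutated bases excluded from the tandem tally")
  }
  pairs <- run_info %>% dplyr::filter(.data$run_length == 2L)
  out <- if (nrow(pairs) == 0) empty else {
    pairs %>%
      dplyr::transmute(
        mutant_id = .data$mutant_id, contig = .data$contig,
        pos5 = .data$run_start,
        ref_dinuc = .data$ref_dinuc, alt_dinuc = .data$alt_dinuc,
        class = classify_tandem(.data$ref_dinuc, .data$alt_dinuc),
        bond_change_5prime = bond_change(substr(.data$ref_dinuc, 1, 1),
                                         substr(.data$alt_dinuc, 1, 1))
      )
  }
  attr(out, "long_runs") <- long_runs
  class(out) <- c("uv_tandems", class(out))
  out
}

#' Summarise tandem mutations per class
#'
#' @param tandems Output of [find_tandems()].
#' @return A tibble with one row per tandem class (`class`, `count`,
#'   `proportion`) plus the total as attribute `total`.
#' @export
tandem_summary <- function(tandems) {
  counts <- table(factor(tandems$class, levels = TANDEM_CLASSES))
  total <- sum(counts)
  out <- tibble::tibble(
    class = TANDEM_CLASSES,
    count = as.integer(counts),
    proportion = if (total > 0) as.integer(counts) / total else NA_real_
  )
  attr(out, "total") <- total
  out
}

#' Summarise tandem mutations per motif
#'
#' Counts per `ref_dinuc -> alt_dinuc` motif on the reference forward
#' strand (strand complementarity deliberately not considered).
#'
#' @param tandems Output of [find_tandems()].
#' @return A tibble: `ref_dinuc`, `alt_dinuc`, `class`,
#'   `bond_change_5prime`, `count`, sorted by decreasing count.
#' @export
tandem_motif_summary <- function(tandems) {
  if (nrow(tandems) == 0) {
    return(tibble::tibble(ref_dinuc = character(), alt_dinuc = character(),
                          class = character(), bond_change_5prime = logical(),
                          count = integer()))
  }
  tibble::as_tibble(tandems) %>%
    dplyr::count(.data$ref_dinuc, .data$alt_dinuc, .data$class,
                 .data$bond_change_5prime, name = "count") %>%
    dplyr::arrange(dplyr::desc(.data$count))
}
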