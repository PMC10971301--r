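# Canonical ordering of the six strand-collapsed substitution classes,
# most to least frequent under UV.
SPECTRUM_CLASSES <- c("G:C→A:T", "A:T→G:C", "A:T→T:A",
                      "G:C→T:A", "A:T→C:G", "G:C→C:G")

# (centre, alt_centre) -> paired class label
paired_class <- function(centre, alt_centre) {
  key <- paste0(centre, alt_centre)
  map <- c(AG = "A:T→G:C", AT = "A:T→T:A", AC = "A:T→C:G",
           CT = "G:C→A:T", CA = "G:C→T:A", CG = "G:C→C:G")
  unname(map[key])
}

#' Collapse substitutions onto the A/C-centred strand
#'
#' Double-stranded DNA makes each substitution readable from either strand;
#' collapsing reports every change with an A or C reference centre (e.g.
#' G→A is reported as C→T on the opposite strand). Substitutions whose
#' reference base is G or T have both alleles complemented.
#'
#' @param ref,alt Character vectors of single reference/alternate bases.
#' @return A tibble with columns `centre` (A or C), `alt_centre`, `cls`
#'   (e.g. `"C→T"`), `cls_paired` (Table-style label, e.g. `"G:C→A:T"`) and
#'   `strand_flipped` (`TRUE` iff the original ref was G or T).
#' @examples
#' collapse_substitution("G", "A") # C→T, paired G:C→A:T, flipped
#' @export
collapse_substitution <- function(ref, alt) {
  assert_bases(ref, "ref"); assert_bases(alt, "alt")
  if (any(ref == alt)) stop("ref must differ from alt", call. = FALSE)
  flip <- ref %in% c("G", "T")
  centre <- ifelse(flip, complement_bases(ref), ref)
  alt_centre <- ifelse(flip, complement_bases(alt), alt)
  tibble::tibble(
    centre = centre,
    alt_centre = alt_centre,
    cls = paste0(centre, "→", alt_centre),
    cls_paired = paired_class(centre, alt_centre),
    strand_flipped = flip
  )
}

# Append collapse columns to a records tibble.
collapse_records <- function(records) {
  assert_records(records)
  dplyr::bind_cols(records, collapse_substitution(records$ref, records$alt))
}

#' Strand-collapsed substitution spectrum
#'
#' Counts mutation records in the six paired substitution classes
#' (G:C→A:T, A:T→G:C, A:T→T:A, G:C→T:A, A:T→C:G, G:C→C:G) and their
#' proportions of the total.
#'
#' @param records Tibble of mutation records (`ref`, `alt` required).
#' @return A tibble of class `uv_spectrum` with columns `class`, `count`,
#'   `proportion`, `percent` (percent rounded to 2 decimals for display;
#'   `proportion` keeps full precision). Proportions are `NA` when the
#'   record set is empty.
#' @export
spectrum_table <- function(records) {
  if (nrow(records) == 0) {
    counts <- stats::setNames(rep(0L, 6), SPECTRUM_CLASSES)
  } else {
    cls <- collapse_substitution(records$ref, records$alt)$cls_paired
    counts <- table(factor(cls, levels = SPECTRUM_CLASSES))
    counts <- stats::setNames(as.integer(counts), SPECTRUM_CLASSES)
  }
  total <- sum(counts)
  prop <- if (total > 0) counts / total else rep(NA_real_, 6)
  out <- tibble::tibble(
    class = SPECTRUM_CLASSES,
    count = unname(counts),
    proportion = unname(prop),
    percent = round(unname(prop) * 100, 2)
  )
  class(out) <- c("uv_spectrum", class(out))
  out
}

#' Per-mutant substitution spectra
#'
#' @param records Records tibble including `mutant_id`.
#' @return A tibble with one spectrum row per (mutant, class).
#' @export
spectrum_by_mutant <- function(records) {
  assert_records(records)
  records %>%
    dplyr::group_by(.data$mutant_id) %>%
    dplyr::group_modify(~ spectrum_table(.x)) %>%
    dplyr::ungroup()
}

#' Transition fraction at an A or C centre
#'
#' Fraction of mutations at the given centre base that are transitions:
#' for A, A:T→G:C over all A-centred classes; for C, G:C→A:T over all
#' C-centred classes.
#'
#' @param spectrum A [spectrum_table()] result.
#' @param centre `"A"` or `"C"`.
#' @return A one-row tibble: `centre`, `n_sites` (centre denominator),
#'   `n_transitions`, `fraction` (`NA` when the denominator is zero).
#' @export
transition_fraction <- function(spectrum, centre = c("A", "C")) {
  centre <- match.arg(centre)
  cls_all <- if (centre == "A") {
    c("A:T→G:C", "A:T→T:A", "A:T→C:G")
  } else {
    c("G:C→A:T", "G:C→T:A", "G:C→C:G")
  }
  cls_ti <- if (centre == "A") "A:T→G:C" else "G:C→A:T"
  denom <- sum(spectrum$count[spectrum$class %in% cls_all])
  num <- sum(spectrum$count[spectrum$class == cls_ti])
  tibble::tibble(
    centre = centre,
    n_sites = denom,
    n_transitions = num,
    fraction = if (denom > 0) num / denom else NA_real_
  )
}
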