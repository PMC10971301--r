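#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

BASES <- c("A", "C", "G", "T")

# Watson-Crick complement, vectorised over character vectors of any length.
complement_bases <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

# Reverse complement of arbitrary-length DNA strings.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_transition <- function(ref, alt) {
  (ref %in% c("A", "G") & alt %in% c("A", "G")) |
    (ref %in% c("C", "T") & alt %in% c("C", "T"))
}

# Watson-Crick pairing bond number: A/T pairs have 2 hydrogen bonds,
# G/C pairs have 3.
bond_number <- function(base) ifelse(base %in% c("A", "T"), 2L, 3L)

#' Does a substitution change the Watson-Crick bond number?
#'
#' A/T pairs hold 2 hydrogen bonds and G/C pairs hold 3. A substitution
#' preserves the bond number only when it swaps partners within the same
#' pairing class (A<->T or C<->G); every other substitution changes it.
#' This is the discriminator separating high- from low-frequency
#' 3'-transition tandem mutations.
#'
#' @param ref,alt Single reference and alternate bases (vectorised).
#' @return Logical vector: `TRUE` when the bond number changes.
#' @examples
#' bond_change("A", "T") # FALSE: both pair with 2 bonds
#' bond_change("A", "C") # TRUE: 2 -> 3
#' @export
bond_change <- function(ref, alt) {
  stopifnot(all(ref %in% BASES), all(alt %in% BASES), all(ref != alt))
  bond_number(ref) != bond_number(alt)
}

assert_bases <- function(x, what = "base") {
  bad <- !(x %in% BASES)
  if (any(bad)) {
    stop(sprintf("invalid %s value(s): %s", what,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# Accept either a DNAStringSet or a (contig, length) data frame wherever
# only contig lengths are needed.
as_genome_lengths <- function(genome) {
  if (is.data.frame(genome)) {
    stopifnot(all(c("contig", "length") %in% names(genome)))
    return(tibble::as_tibble(genome[, c("contig", "length")]))
  }
  genome_lengths(genome)
}

# Validate a records tibble has the expected columns.
assert_records <- function(records) {
  needed <- c("mutant_id", "contig", "pos", "ref", "alt")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop("records is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(records)
}
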