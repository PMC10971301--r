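#' Contingency table of 3'-neighbour class vs adenine substitution type
#'
#' Restricted to strand-collapsed A-centred records with class A→G or A→T
#' (A→C and all C-centred records are excluded). Rows split the 3'
#' neighbour (read in collapsed orientation) into purines (A+G) and
#' pyrimidines (T+C); contig-edge sites without a 3' neighbour are
#' dropped.
#'
#' @param records Records tibble.
#' @param genome `DNAStringSet` reference.
#' @return A 2x2 integer matrix of class `uv_contingency` with dimnames
#'   `three_prime` = (`A+G`, `T+C`) and `substitution` = (`A→G`, `A→T`).
#' @export
build_contingency <- function(records, genome) {
  ctx <- extract_context(records, genome)
  eligible <- ctx %>%
    dplyr::filter(!.data$at_edge, .data$centre == "A",
                  .data$cls %in% c("A→G", "A→T"))
  row_lab <- ifelse(eligible$three_prime %in% c("A", "G"), "A+G", "T+C")
  tab <- table(factor(row_lab, levels = c("A+G", "T+C")),
               factor(eligible$cls, levels = c("A→G", "A→T")))
  m <- matrix(as.integer(tab), nrow = 2,
              dimnames = list(three_prime = c("A+G", "T+C"),
                              substitution = c("A→G", "A→T")))
  class(m) <- c("uv_contingency", class(m))
  m
}

#' Contingency table from four cell counts
#'
#' Convenience constructor for [pearson_chi_square()]: `a`,`b` form the
#' purine row (A→G, A→T), `c`,`d` the pyrimidine row.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return A `uv_contingency` matrix.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  m <- matrix(as.integer(c(a, c, b, d)), nrow = 2,
              dimnames = list(three_prime = c("A+G", "T+C"),
                              substitution = c("A→G", "A→T")))
  if (any(m < 0)) stop("cell counts must be non-negative", call. = FALSE)
  class(m) <- c("uv_contingency", class(m))
  m
}

#' Pearson chi-square test on a 2x2 table
#'
#' Closed form: `N (ad - bc)^2 / (r1 r2 c1 c2)` with 1 degree of freedom;
#' no continuity correction by default (Yates optional).
#'
#' @param tab A 2x2 matrix (e.g. from [build_contingency()]).
#' @param correct Apply the Yates continuity correction.
#' @return An object of class `uv_chisq`: `statistic`, `df`, `p.value`,
#'   `table`, `correct`. `NA` statistic with a warning when a marginal is
#'   zero.
#' @export
pearson_chi_square <- function(tab, correct = FALSE) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2, 2)))
  a <- as.numeric(tab[1, 1]); b <- as.numeric(tab[1, 2])
  c <- as.numeric(tab[2, 1]); d <- as.numeric(tab[2, 2])
  N <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0)) {
    warning("zero marginal total; chi-square undefined", call. = FALSE)
    stat <- NA_real_
  } else {
    num <- abs(a * d - b * c)
    if (correct) num <- max(0, num - N / 2)
    stat <- N * num^2 / (r1 * r2 * c1 * c2)
  }
  out <- list(statistic = stat, df = 1L,
              p.value = if (is.na(stat)) NA_real_ else
                stats::pchisq(stat, 1L, lower.tail = FALSE),
              table = tab, correct = correct)
  class(out) <- "uv_chisq"
  out
}

#' @export
print.uv_chisq <- function(x, ...) {
  cat("Pearson chi-square test (2x2",
      if (x$correct) ", Yates-corrected" else "", ")\n", sep = "")
  print(unclass(x$table))
  cat(sprintf("  X-squared = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}
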