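#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a chi-square test result
#'
#' @param x A `uv_chisq` object from [pearson_chi_square()].
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `method`.
#' @method tidy uv_chisq
#' @export
tidy.uv_chisq <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = x$df, p.value = x$p.value,
    method = paste0("Pearson chi-square (2x2",
                    if (x$correct) ", Yates-corrected", ")")
  )
}

#' @rdname tidy.uv_chisq
#' @method glance uv_chisq
#' @export
glance.uv_chisq <- function(x, ...) tidy(x, ...)

#' Tidy a contingency table
#'
#' @param x A `uv_contingency` matrix.
#' @param ... Unused.
#' @return A tibble in long form: `three_prime`, `substitution`, `count`.
#' @method tidy uv_contingency
#' @export
tidy.uv_contingency <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)
  names(df) <- c("three_prime", "substitution", "count")
  tibble::as_tibble(df)
}

#' Tidy a uniformity diagnostic
#'
#' @param x A `uv_uniformity` object from [uniformity_test()].
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `n_bins`,
#'   `n_sites`, `bin_size`.
#' @method tidy uv_uniformity
#' @export
tidy.uv_uniformity <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
                 n_bins = x$n_bins, n_sites = x$n_sites,
                 bin_size = x$bin_size)
}

#' @rdname tidy.uv_uniformity
#' @method glance uv_uniformity
#' @export
glance.uv_uniformity <- function(x, ...) tidy(x, ...)
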