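#' Plot a substitution spectrum
#'
#' Bar chart of the six strand-collapsed class proportions.
#'
#' @param object A [spectrum_table()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot uv_spectrum
#' @export
autoplot.uv_spectrum <- function(object, ...) {
  df <- tibble::as_tibble(object) %>%
    dplyr::mutate(class = factor(.data$class, levels = .data$class))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$percent)) +
    ggplot2::geom_col(fill = "#4477AA") +
    ggplot2::labs(x = NULL, y = "% of substitutions",
                  title = "Strand-collapsed substitution spectrum") +
    ggplot2::theme_minimal()
}

#' Plot flanking-base standardized mutation frequencies
#'
#' One panel per flank side, frequency bars per flank base, coloured by
#' substitution class.
#'
#' @param freq_tbl Output of [context_frequency_table()].
#' @return A ggplot object.
#' @export
plot_context_frequencies <- function(freq_tbl) {
  ggplot2::ggplot(freq_tbl,
                  ggplot2::aes(x = .data$flank_base, y = .data$frequency,
                               fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~side) +
    ggplot2::labs(x = "flanking base",
                  y = "standardized mutation frequency (n/N × 10⁶)") +
    ggplot2::theme_minimal()
}

#' Plot mutation positions along contigs
#'
#' One horizontal panel per contig with a tick per mutated site — a
#' compact genome-wide distribution view.
#'
#' @param track Output of [position_track()].
#' @return A ggplot object.
#' @export
plot_position_track <- function(track) {
  ggplot2::ggplot(track, ggplot2::aes(x = .data$pos, y = 0)) +
    ggplot2::geom_point(shape = "|", size = 3, colour = "#CC3311") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$contig), switch = "y") +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "position (bp)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot tandem-mutation class counts
#'
#' @param tandems Output of [find_tandems()].
#' @return A ggplot object.
#' @export
plot_tandem_classes <- function(tandems) {
  df <- tandem_summary(tandems)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$count)) +
    ggplot2::geom_col(fill = "#228833") +
    ggplot2::labs(x = NULL, y = "tandem mutations") +
    ggplot2::theme_minimal()
}
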