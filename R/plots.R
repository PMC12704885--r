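#' Plot entropy spectra
#'
#' One curve per document over the alpha grid, coloured by group. The
#' non-increasing shape in alpha is the fingerprint of a non-uniform
#' word-frequency distribution.
#'
#' @param object An `entropy_spectra` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot entropy_spectra
#' @export
autoplot.entropy_spectra <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$alpha,
                                       y = .data$entropy_bits,
                                       group = .data$doc_id,
                                       colour = .data$group)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = expression(alpha), y = "Entropy (bits)",
                  colour = "Group") +
    ggplot2::theme_minimal()
}

#' Plot paired entropy differences across alpha
#'
#' Per-pair difference curves (guardian minus minor) with the cross-pair
#' mean overlaid; the decrease with alpha shows the vocabulary-size gap
#' (low alpha) closing at frequency-weighted orders.
#'
#' @param deltas Output of [paired_deltas()].
#' @return A ggplot.
#' @export
plot_delta_curve <- function(deltas) {
  means <- dplyr::summarise(dplyr::group_by(deltas, .data$alpha),
                            delta = mean(.data$delta), .groups = "drop")
  ggplot2::ggplot(deltas, ggplot2::aes(x = .data$alpha, y = .data$delta)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$pair_id),
                       alpha = 0.3, colour = "grey50") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_line(data = means, colour = "black", linewidth = 1) +
    ggplot2::labs(x = expression(alpha),
                  y = expression(Delta ~ "(guardian - minor, bits)")) +
    ggplot2::theme_minimal()
}

#' Plot per-word Shannon entropy contributions
#'
#' @param table A `freq_table`.
#' @param top_n Number of highest-probability words to show (default 30).
#' @return A ggplot.
#' @export
plot_word_contributions <- function(table, top_n = 30) {
  wc <- head(word_contributions(table), top_n)
  wc$token <- factor(wc$token, levels = rev(wc$token))
  ggplot2::ggplot(wc, ggplot2::aes(x = .data$contribution_bits,
                                   y = .data$token)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Shannon entropy contribution (bits)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an analysis report
#'
#' The paired difference curve when pairs are present, otherwise the
#' spectra of all documents.
#'
#' @param object An `analysis_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot analysis_report
#' @export
autoplot.analysis_report <- function(object, ...) {
  if (!is.null(object$deltas)) {
    plot_delta_curve(object$deltas)
  } else {
    autoplot(object$spectra)
  }
}
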