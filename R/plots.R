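# ggplot2 views of the main result types.

#' Plot sliding-window nucleotide diversity
#'
#' @param windows Output of [sliding_pi()].
#' @return A ggplot: Pi against window start, colored by region.
#' @export
plot_sliding_pi <- function(windows) {
  ggplot2::ggplot(windows, ggplot2::aes(x = .data$start, y = .data$pi,
    color = .data$region)) +
    ggplot2::geom_line(ggplot2::aes(group = 1), color = "grey70") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "alignment position (window start)",
      y = expression(pi), color = "region") +
    ggplot2::theme_minimal()
}

#' ENC-GC3 plot with the expected curve
#'
#' @param tab Output of [enc_gc3_table()].
#' @param highlight Optional character vector of gene names drawn in red
#'   (e.g. screened markers).
#' @return A ggplot of ENC against GC3s with the null expectation curve.
#' @export
plot_enc_gc3 <- function(tab, highlight = NULL) {
  curve <- tibble(s = seq(0.01, 0.99, by = 0.01))
  curve$enc <- pmin(enc_expected(curve$s), 61)
  tab$highlight <- !is.null(highlight) & tab$gene %in% highlight
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$gc3s, y = .data$enc)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(x = .data$s, y = .data$enc),
      inherit.aes = FALSE) +
    ggplot2::geom_point(ggplot2::aes(color = .data$highlight), show.legend = FALSE) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
    ggplot2::labs(x = "GC3s", y = "ENC") +
    ggplot2::ylim(20, 62) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heat map of a pairwise matrix
#'
#' @param object A `pair_matrix` (ALS, indel counts, mean Pi, p-distance).
#' @param ... Unused.
#' @return A ggplot tile map.
#' @export
#' @method autoplot pair_matrix
autoplot.pair_matrix <- function(object, ...) {
  long <- tidy(object)
  long2 <- bind_rows(long, dplyr::rename(long, a = "b", b = "a"))
  ggplot2::ggplot(long2, ggplot2::aes(x = .data$a, y = .data$b,
    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = NULL, y = NULL, fill = attr(object, "statistic")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
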