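# ggplot2 views of the main result types.

#' Volcano plot of a differential screen
#'
#' @param de A `sponge_de` tibble (screened).
#' @param lfc_threshold,p_threshold Thresholds drawn as guide lines.
#' @return A ggplot.
#' @export
plot_volcano <- function(de, lfc_threshold = 1, p_threshold = 0.05) {
  d <- tidy(de)
  if (!"direction" %in% names(d)) d <- tidy(screen_de(de, lfc_threshold, p_threshold))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc,
                                  y = -log10(pmax(.data$p_value, 1e-300)),
                                  colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-lfc_threshold, lfc_threshold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(p_threshold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(up = "#d73027", down = "#4575b4",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (HF / LF)", y = "-log10 p",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot sponge_de
#' @export
autoplot.sponge_de <- function(object, ...) plot_volcano(object, ...)

#' Bar chart of read-filter accounting
#'
#' @param report A `filter_report` from [filter_reads()] / [collapse_tags()].
#' @return A ggplot.
#' @export
plot_filter_report <- function(report) {
  d <- tibble::as_tibble(report)
  d$category <- factor(d$category, levels = rev(FILTER_CATEGORIES))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$percent)) +
    ggplot2::geom_col(fill = "#74add1") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of reads") +
    ggplot2::theme_minimal()
}

#' @method autoplot filter_report
#' @export
autoplot.filter_report <- function(object, ...) plot_filter_report(object)

#' Histogram of clean-tag insert lengths
#'
#' @param dist A `tag_length_dist` from [length_distribution()].
#' @return A ggplot.
#' @export
plot_length_distribution <- function(dist) {
  ggplot2::ggplot(tibble::as_tibble(dist),
                  ggplot2::aes(x = .data$length, y = .data$count)) +
    ggplot2::geom_col(fill = "#66bd63") +
    ggplot2::labs(x = "insert length (nt)", y = "reads") +
    ggplot2::theme_minimal()
}

#' @method autoplot tag_length_dist
#' @export
autoplot.tag_length_dist <- function(object, ...) plot_length_distribution(object)

#' Dot plot of over-representation results
#'
#' @param res Result tibble from [ora()].
#' @param top Number of top terms shown.
#' @return A ggplot.
#' @export
plot_ora <- function(res, top = 15) {
  d <- head(res, top)
  d$term_name <- factor(d$term_name, levels = rev(d$term_name))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(pmax(.data$p_value, 1e-300)),
                                  y = .data$term_name, size = .data$k)) +
    ggplot2::geom_point(colour = "#d73027") +
    ggplot2::labs(x = "-log10 p", y = NULL, size = "hits") +
    ggplot2::theme_minimal()
}
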