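# ggplot2 helpers for the main result types ---------------------------------

#' Plot a windowed statistic along the genome
#'
#' @param stats Window-stat tibble from [windowed_scan()], [tajimas_d()] or
#'   [wc_fst()].
#' @return A ggplot: window midpoint vs value, faceted by chromosome.
#' @export
plot_window_stats <- function(stats) {
  df <- dplyr::mutate(stats, mid = (.data$start + .data$end) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$value)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE, alpha = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = unique(stats$stat))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a site frequency spectrum
#'
#' One population: barplot of counts by derived/minor allele count. Two
#' populations: heatmap of the joint spectrum.
#'
#' @param object An `sfs_array`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sfs_array <- function(object, ...) {
  df <- tidy(object)
  pops <- attr(object, "pops")
  if (length(pops) == 1) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data[[pops[1]]], y = .data$n)) +
      ggplot2::geom_col() +
      ggplot2::labs(
        x = sprintf("%s allele count (%s)", attr(object, "polarization"), pops[1]),
        y = "sites"
      )
  } else {
    ggplot2::ggplot(df, ggplot2::aes(
      x = .data[[pops[1]]], y = .data[[pops[2]]], fill = .data$n
    )) +
      ggplot2::geom_tile() +
      ggplot2::labs(x = pops[1], y = pops[2], fill = "sites")
  }
}
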