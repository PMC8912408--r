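# autoplot() methods for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a quadripartite partition as a linear region map
#'
#' @param object A `quadripartite_partition`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot quadripartite_partition
#' @export
autoplot.quadripartite_partition <- function(object, ...) {
  d <- tidy(object)
  d$region <- factor(d$region, levels = c("LSC", "IRb", "SSC", "IRa"))
  ggplot2::ggplot(d, ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                  ymin = 0, ymax = 1, fill = .data$region)) +
    ggplot2::geom_rect(colour = "grey20") +
    ggplot2::geom_text(ggplot2::aes(x = (.data$start + .data$end) / 2, y = 0.5,
                                    label = paste0(.data$region, "\n",
                                                   .data$length, " bp")),
                       size = 3) +
    ggplot2::scale_fill_brewer(palette = "Pastel1", guide = "none") +
    ggplot2::labs(x = "position (bp, canonical rotation)", y = NULL,
                  title = object$identifier) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot junction depth QC medians
#'
#' @param object A `junction_qc_report`.
#' @param ... Unused.
#' @return A ggplot of left/inner/right window medians per junction.
#' @method autoplot junction_qc_report
#' @export
autoplot.junction_qc_report <- function(object, ...) {
  d <- tidyr::pivot_longer(tibble::as_tibble(object),
                           c("left_median", "inner_median", "right_median"),
                           names_to = "window", values_to = "median_depth")
  d$window <- factor(d$window,
                     levels = c("left_median", "inner_median", "right_median"),
                     labels = c("left", "inner", "right"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$junction, y = .data$median_depth,
                                  fill = .data$window)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(data = tibble::as_tibble(object),
                       ggplot2::aes(x = .data$junction, y = 0,
                                    label = .data$flag),
                       inherit.aes = FALSE, vjust = 1.4, size = 3) +
    ggplot2::labs(x = NULL, y = "median depth",
                  title = attr(object, "identifier")) +
    ggplot2::theme_minimal()
}

#' Plot site concordance factors per branch
#'
#' @param object A tibble of `concordance_result` rows (e.g. from
#'   [site_concordance_all()]).
#' @param ... Unused.
#' @return A stacked ggplot of sCF/sDF1/sDF2 per branch.
#' @method autoplot concordance_result
#' @export
autoplot.concordance_result <- function(object, ...) {
  d <- tidyr::pivot_longer(tibble::as_tibble(object),
                           c("scf", "sdf1", "sdf2"),
                           names_to = "component", values_to = "percent")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$branch), y = .data$percent,
                                  fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(scf = "#7b5aa6", sdf1 = "#d95f02",
                                          sdf2 = "#e6ab02")) +
    ggplot2::labs(x = "internal branch", y = "percent of decisive sites") +
    ggplot2::theme_minimal()
}
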