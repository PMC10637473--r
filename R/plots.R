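#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of per-sex information components
#'
#' One point-range per reaction and sex: the IC point estimate with its
#' credibility interval, a dashed reference line at IC = 0 (the signal
#' threshold for the lower bound). Reactions absent in a stratum are dropped
#' from that stratum's ranges.
#'
#' @param x A `sexsig_comparison` from [run_comparison()].
#' @return A ggplot object.
#' @export
plot_ic_forest <- function(x) {
  d <- tidy(x) |> dplyr::filter(!is.na(.data$ic))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ic, y = .data$reaction_pt,
                                  colour = .data$sex)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ic025, xmax = .data$ic975),
      position = ggplot2::position_dodge(width = 0.6), linewidth = 0.4, size = 0.3
    ) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$soc_code),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "Information component (log2 O/E, 95% CrI)", y = NULL,
                  colour = "Sex",
                  title = attr(x, "drug") %||% NULL) +
    ggplot2::theme_minimal(base_size = 10)
}

#' Heatmap of per-sex information components
#'
#' Reaction-by-sex tile map filled by the IC point estimate; strata in which
#' the reaction was never co-reported are blank.
#'
#' @param x A `sexsig_comparison` from [run_comparison()].
#' @return A ggplot object.
#' @export
plot_ic_heatmap <- function(x) {
  d <- tidy(x)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sex, y = .data$reaction_pt,
                                  fill = .data$ic)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  na.value = "grey90") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$soc_code),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "IC",
                  title = attr(x, "drug") %||% NULL) +
    ggplot2::theme_minimal(base_size = 10)
}

#' @rdname plot_ic_forest
#' @param object A `sexsig_comparison`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.sexsig_comparison <- function(object, ...) plot_ic_forest(object)
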