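# Plots: fitted-vs-observed index scatter and topology-vs-stress trends.

#' Fitted versus observed mean CSCI
#'
#' Scatter of the index model's fitted values against the observed group
#' mean CSCI, colored by group mean land use, with the 1:1 line.
#'
#' @param model an `index_model` from [fit_index_model()].
#' @return a ggplot object.
#' @export
plot_model_fit <- function(model) {
  d <- model$data
  d$fitted_csci <- predict(model, d)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_csci, y = .data$fitted_csci,
                                  colour = .data$mean_landuse_pct)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_point(alpha = 0.6, size = 1.3) +
    ggplot2::scale_colour_viridis_c(name = "Mean land use (%)") +
    ggplot2::labs(x = "Observed mean CSCI", y = "Modeled mean CSCI") +
    ggplot2::theme_minimal()
}

#' @method autoplot index_model
#' @export
autoplot.index_model <- function(object, ...) plot_model_fit(object)

#' Topology measures along the land-use gradient
#'
#' One panel per topology measure against group mean land use, with a
#' linear trend line.
#'
#' @param topology the per-group topology table of a `pipeline_result`.
#' @return a ggplot object.
#' @export
plot_topology_trends <- function(topology) {
  metrics <- c("n_taxa", "connectance", "mean_strength", "modularity",
               "degree_heterogeneity")
  long <- tidyr::pivot_longer(
    topology[c("mean_landuse_pct", metrics)],
    dplyr::all_of(metrics), names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mean_landuse_pct,
                                     y = .data$value)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "firebrick",
                         linewidth = 0.6) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "Group mean developed land use (%)", y = NULL) +
    ggplot2::theme_minimal()
}
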