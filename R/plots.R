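#' Plot a nearest-taxon-index time series
#'
#' Per-sample NTI against layer year, coloured by lake, with the approximate
#' two-sided significance band at +/- 1.96 for reference; individual
#' classifications come from each sample's empirical null quantiles and are
#' shown by point shape.
#'
#' @param nti An `nti_tbl` from [nti_series()].
#' @return A ggplot object.
#' @export
plot_nti_series <- function(nti) {
  ggplot2::ggplot(nti, ggplot2::aes(x = .data$year, y = .data$nti,
                                    colour = .data$lake_id,
                                    shape = .data$classification)) +
    ggplot2::geom_hline(yintercept = c(-1.96, 1.96), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(clustered = 17, random = 1,
                                           overdispersed = 25)) +
    ggplot2::labs(x = "Year", y = "Nearest taxon index (NTI)",
                  colour = "Lake", shape = "Structure") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.nti_tbl <- function(object, ...) plot_nti_series(object)

#' Plot a distance-decay relationship
#'
#' Scatter of the pairwise beta-diversity values against the predictor with
#' the fitted OLS line.
#'
#' @param fit A `decay_fit` from [distance_decay()].
#' @return A ggplot object.
#' @export
plot_distance_decay <- function(fit) {
  g <- glance(fit)
  ggplot2::ggplot(fit$data,
                  ggplot2::aes(x = .data[[fit$predictor]],
                               y = .data[[fit$response]])) +
    ggplot2::geom_point(alpha = 0.35, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "black", linewidth = 0.6) +
    ggplot2::labs(
      x = fit$predictor, y = fit$response,
      subtitle = sprintf("slope = %.3g, p = %.3g, adj R² = %.3g, n = %d",
                         g$slope, g$p_slope, g$adj_r_squared, g$n)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.decay_fit <- function(object, ...) plot_distance_decay(object)
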