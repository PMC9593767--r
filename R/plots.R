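# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a clustering stability scan
#'
#' Mean subsampled ARI per resolution with a +-1 sd ribbon; the selected
#' resolution (first-decline rule) is marked with a dashed line.
#'
#' @param object A `stability_table` from [stability_scan()].
#' @param delta Decline threshold passed to [select_resolution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_table <- function(object, delta = 0.05, ...) {
  s <- stability_summary(object)
  sel <- select_resolution(object, delta = delta)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$resolution, y = .data$mean_ari)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_ari - .data$sd_ari,
                                      ymax = .data$mean_ari + .data$sd_ari),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = sel, linetype = "dashed") +
    ggplot2::labs(x = "resolution", y = "mean ARI (subsample vs reference)",
                  title = "Clustering stability scan") +
    ggplot2::theme_minimal()
}

#' Plot consensus NMF rank-selection metrics
#'
#' @param object A `rank_metrics` tibble from [consensus_metrics()].
#' @param ... Unused.
#' @return A ggplot object faceted by metric.
#' @export
autoplot.rank_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("cophenetic", "rss", "dispersion", "silhouette"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "rank", title = "Consensus NMF rank metrics") +
    ggplot2::theme_minimal()
}

#' Plot estimated cell-type composition per sample
#'
#' @param object A `deconv_result` from [deconvolve()].
#' @param ... Unused.
#' @return A stacked-bar ggplot of estimated fractions.
#' @export
autoplot.deconv_result <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                                     fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "estimated fraction",
                  title = "Deconvolved cell-type composition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot the fitted score mixture of a Gaussian-mixture fit
#'
#' Histogram of the scored values with the two fitted component densities
#' overlaid.
#'
#' @param object A `gmm1d` from [fit_gmm_1d()].
#' @param values The scored values the model was fitted to.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gmm1d <- function(object, values, ...) {
  grid <- seq(min(values, na.rm = TRUE), max(values, na.rm = TRUE),
              length.out = 200)
  dens <- dplyr::bind_rows(lapply(1:2, function(k) {
    tibble::tibble(component = factor(k), x = grid,
                   density = object$weights[k] *
                     stats::dnorm(grid, object$means[k],
                                  sqrt(object$variances[k])))
  }))
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = tibble::tibble(x = values),
      ggplot2::aes(x = .data$x, y = ggplot2::after_stat(density)),
      bins = 50, fill = "grey80") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(x = .data$x, y = .data$density,
                                    color = .data$component)) +
    ggplot2::labs(x = "score", y = "density",
                  title = "Two-component mixture of the apoptotic score") +
    ggplot2::theme_minimal()
}

#' Plot shock probability against the exposure, stratified by the modifier
#'
#' @param fit A `logit_fit` from [logistic_irls()].
#' @param ... Passed to [stratified_effect_curve()].
#' @return A ggplot object with one curve per modifier stratum.
#' @export
plot_effect_modification <- function(fit, ...) {
  curve <- stratified_effect_curve(fit, ...)
  curve$stratum <- sprintf("%s = %.3g (q%.0f%%)", fit$modifier,
                           curve$modifier_value,
                           100 * curve$modifier_quantile)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$exposure,
                                      y = .data$probability,
                                      color = .data$stratum)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = fit$exposure, y = "P(shock)",
                  title = "Effect modification of the shock risk") +
    ggplot2::theme_minimal()
}
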