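#' Plot the exchange-search descent
#'
#' One non-increasing line of accepted criterion values per restart.
#'
#' @param object `exchange_result` from [exchange_search()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.exchange_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$value,
                               colour = factor(.data$restart))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "exchange iteration", y = "criterion value",
                  colour = "restart") +
    ggplot2::theme_minimal()
}

#' Trace plot of MCMC draws
#'
#' @param object `optimet_chains` object.
#' @param genotypes Genotype ids to show (default: first 4).
#' @param ... Unused.
#' @return A ggplot object faceted by parameter.
#' @export
autoplot.optimet_chains <- function(object, genotypes = NULL, ...) {
  if (is.null(genotypes)) genotypes <- head(object$genotype_ids, 4)
  d <- tidy(object, retained_only = FALSE) |>
    dplyr::filter(.data$genotype_id %in% genotypes)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$value,
                                  colour = .data$genotype_id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = object$burn_in, linetype = "dashed") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = "value", colour = "variety") +
    ggplot2::theme_minimal()
}

#' Strategy comparison plot for a pipeline run
#'
#' Boxplots of the across-parameter mean of one metric per strategy, the
#' pipeline's headline comparison.
#'
#' @param object `optimet_pipeline` object.
#' @param metric Metric to plot (default `"nrmse"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.optimet_pipeline <- function(object, metric = "nrmse", ...) {
  d <- object$report |>
    dplyr::filter(.data$parameter == "mean", .data$metric == .env$metric)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$strategy, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5,
                         ggplot2::aes(colour = factor(.data$year))) +
    ggplot2::labs(x = NULL, y = metric, colour = "year") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
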