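#' Range-normalized root-mean-square error of parameter estimates
#'
#' \eqn{\mathrm{NRMSE}(\theta_s) = [\frac{1}{I}\sum_i ((\hat\theta_{is} -
#' \theta_{is}) / (M_s - m_s))^2]^{1/2}} per parameter. Against simulated
#' truth the ranges are the prior bounds; against full-data reference
#' estimates, pass the observed reference ranges and the same formula is
#' the reference-normalized variant (NRMSE*).
#'
#' @param estimates Tibble `genotype_id` + one column per parameter.
#' @param truth Tibble of the same shape (true or reference values).
#' @param ranges Named numeric vector of per-parameter ranges
#'   `M_s - m_s`, or a bounds tibble ([default_bounds()]).
#' @return Tibble `parameter`, `nrmse`.
#' @export
nrmse <- function(estimates, truth, ranges = default_bounds()) {
  if (is.data.frame(ranges)) {
    rg <- setNames(ranges$upper - ranges$lower, ranges$parameter)
  } else {
    rg <- ranges
  }
  if (any(rg <= 0)) stop_invalid("parameter ranges must be positive")
  pars <- names(rg)
  if (!all(pars %in% names(estimates)) || !all(pars %in% names(truth))) {
    stop_invalid("estimates/truth must carry columns: ",
                 paste(pars, collapse = ", "))
  }
  m <- match(estimates$genotype_id, truth$genotype_id)
  if (anyNA(m)) stop_invalid("line sets do not match")
  purrr::map_dfr(pars, function(s) {
    err <- (estimates[[s]] - truth[[s]][m]) / rg[[s]]
    tibble::tibble(parameter = s, nrmse = sqrt(mean(err^2)))
  })
}

#' Observed ranges of reference estimates
#'
#' Per-parameter `max - min` over a reference estimate table; the
#' normalizer for NRMSE* and NPSE when comparing against full-data
#' reference estimates rather than simulated truth.
#'
#' @param reference Tibble `genotype_id` + one column per parameter.
#' @param parameters Parameter column names.
#' @return Named numeric vector of ranges.
#' @export
reference_ranges <- function(reference, parameters = c("VAI", "SLDL", "Phyl")) {
  setNames(purrr::map_dbl(parameters,
                          ~diff(range(reference[[.x]]))), parameters)
}

#' Normalized posterior square error
#'
#' Posterior-expected normalized squared deviation from reference values,
#' per parameter: \eqn{\frac{1}{I}\sum_i \frac{1}{K}\sum_k
#' ((\theta_{is}^k - \theta^*_{is}) / (M^*_s - m^*_s))^2} over all K
#' retained draws. Unlike NRMSE of a point estimate it also charges the
#' posterior spread: NPSE = range-scaled squared bias of the posterior
#' mean + posterior variance.
#'
#' @param chains `optimet_chains` object.
#' @param reference Tibble `genotype_id` + one column per parameter.
#' @param ranges Named per-parameter ranges; defaults to the observed
#'   ranges of `reference`.
#' @return Tibble `parameter`, `npse`.
#' @export
npse <- function(chains, reference, ranges = NULL) {
  keep <- retained_iterations(chains)
  if (length(keep) < 100) stop_invalid("need >= 100 retained draws")
  if (is.null(ranges)) ranges <- reference_ranges(reference, chains$parameters)
  if (any(ranges <= 0)) stop_invalid("parameter ranges must be positive")
  m <- match(chains$genotype_ids, reference$genotype_id)
  if (anyNA(m)) {
    stop_invalid("reference is missing line(s): ",
                 paste(chains$genotype_ids[is.na(m)], collapse = ", "))
  }
  purrr::map_dfr(seq_along(chains$parameters), function(s) {
    par <- chains$parameters[s]
    draws <- chains$theta[keep, , s, drop = FALSE] # K x I
    ref <- reference[[par]][m]
    dev <- sweep(draws[, , 1, drop = FALSE], 2, ref)[, , 1] / ranges[[par]]
    tibble::tibble(parameter = par, npse = mean(dev^2))
  })
}

#' Prediction accuracy (Pearson correlation)
#'
#' @param predicted,observed Numeric vectors (>= 3 pairs, non-constant).
#' @return Correlation in \[-1, 1\].
#' @export
prediction_accuracy <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 3) {
    stop_invalid("need >= 3 matched pairs")
  }
  if (sd(predicted) == 0 || sd(observed) == 0) {
    stop_invalid("correlation undefined for a constant vector")
  }
  cor(predicted, observed)
}

#' Summarize metrics across designs, years and parameters
#'
#' Stacks per-design metric records into a long table and appends the
#' across-parameter means (one `mean` row per design x year x metric),
#' the quantity design strategies are ranked by.
#'
#' @param records Tibble with columns `design_id`, `strategy`, `year`,
#'   `parameter`, `metric`, `value` (extra columns pass through).
#' @return A tibble of the input rows plus rows with
#'   `parameter = "mean"` holding the across-parameter average, and a
#'   `strategy_mean` column giving the per-strategy average of those
#'   means.
#' @export
summarize_design_run <- function(records) {
  needed <- c("design_id", "strategy", "year", "parameter", "metric", "value")
  if (!all(needed %in% names(records))) {
    stop_invalid("records must carry columns: ", paste(needed, collapse = ", "))
  }
  means <- records |>
    dplyr::group_by(.data$design_id, .data$strategy, .data$year,
                    .data$metric) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::mutate(parameter = "mean")
  out <- dplyr::bind_rows(records[, needed], means[, needed])
  strat <- out |>
    dplyr::filter(.data$parameter == "mean") |>
    dplyr::group_by(.data$strategy, .data$metric) |>
    dplyr::summarise(strategy_mean = mean(.data$value), .groups = "drop")
  dplyr::left_join(out, strat, by = c("strategy", "metric"))
}
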