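#' Phenology model constants
#'
#' Non-genetic constants of the three-phase heading model. Thermal time is
#' accumulated above a 0 deg C base. Defaults: 150 degree-days from sowing
#' to emergence (`tt_em`); from emergence, a baseline vernalization rate
#' `vbee` of 0.01 per day with the temperature response active between
#' `vern_t_min` and `vern_t_max` (temperatures outside the window are
#' clamped to it);
#' a base final leaf number `l_base` of 8 leaves increased by (i) the
#' day-length response when day length at vernalization saturation falls
#' short of `dl_sat` hours and (ii) a vernalization leaf delay -- a
#' fraction `vern_leaf_frac` of the leaves emerged between emergence and
#' vernalization saturation is added to the final leaf number, so slow
#' vernalization delays the flag leaf directly; and `n_tail` extra
#' phyllochrons from flag-leaf ligule to heading.
#'
#' @param tt_em Sowing-to-emergence thermal duration (degree-days).
#' @param vbee Baseline daily vernalization rate (1/day).
#' @param vern_t_min,vern_t_max Effective temperature window for
#'   vernalization (deg C); daily temperature is clamped into it.
#' @param l_base Base final leaf number (leaves).
#' @param dl_sat Saturating day length (h); no photoperiod delay above it.
#' @param n_tail Phyllochrons from ligule appearance to heading.
#' @param vern_leaf_frac Fraction of pre-saturation emergence-phase thermal
#'   time added to the leaf-phase target (leaves delayed by incomplete
#'   vernalization).
#' @return A named list of constants.
#' @export
cgm_constants <- function(tt_em = 150, vbee = 0.01,
                          vern_t_min = 0, vern_t_max = 18,
                          l_base = 8, dl_sat = 15, n_tail = 2,
                          vern_leaf_frac = 0.5) {
  list(tt_em = tt_em, vbee = vbee, vern_t_min = vern_t_min,
       vern_t_max = vern_t_max, l_base = l_base, dl_sat = dl_sat,
       n_tail = n_tail, vern_leaf_frac = vern_leaf_frac)
}

#' Default genetic-parameter bounds
#'
#' Expert prior bounds for the three genetic parameters: VAI (response of
#' vernalization rate to temperature, 1/(day degC)) in \[0, 0.01\]; SLDL
#' (day-length response of leaf production, leaves/h) in \[0, 1\]; Phyl
#' (phyllochron, degree-days/leaf) in \[80, 120\].
#'
#' @return A tibble `parameter`, `lower`, `upper`.
#' @export
default_bounds <- function() {
  tibble::tibble(parameter = c("VAI", "SLDL", "Phyl"),
                 lower = c(0, 0, 80),
                 upper = c(0.01, 1, 120))
}

check_bounds <- function(bounds) {
  stopifnot(all(c("parameter", "lower", "upper") %in% names(bounds)))
  if (any(bounds$upper <= bounds$lower)) {
    stop_invalid("each parameter needs `lower` < `upper`")
  }
  bounds
}

as_theta_matrix <- function(theta, bounds) {
  p <- nrow(bounds)
  if (is.data.frame(theta)) theta <- as.matrix(theta[, bounds$parameter])
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  if (ncol(theta) != p) {
    stop_invalid("theta must have ", p, " columns (",
                 paste(bounds$parameter, collapse = ", "), ")")
  }
  storage.mode(theta) <- "double"
  theta
}

# Heading times for a matrix of parameter vectors over a tibble of
# environments; negative return codes (horizon exhausted) are kept as-is
# for callers that treat them as impossible parameter values.
heading_matrix <- function(theta, envs, constants = cgm_constants(),
                           bounds = default_bounds()) {
  theta <- as_theta_matrix(theta, bounds)
  cpp_heading_matrix(theta, envs$tmean_c, envs$daylength_h, constants)
}

no_heading_phase <- c(`-1` = "emergence", `-2` = "vernalization",
                      `-3` = "leaf phase")

#' Simulate heading date for one variety in one environment
#'
#' Runs the three-phase phenology model: cumulative thermal time (base
#' 0 deg C) reaches `tt_em` at emergence; from the emergence instant,
#' vernalization accumulates daily at rate `vbee + VAI * T` (T clamped to
#' the effective window) until it saturates at 1; the final leaf number is
#' `l_base + vern_delay + SLDL * max(0, dl_sat - DL)` with DL the day
#' length on the day vernalization saturates (or the emergence day if
#' later) and `vern_delay` the vernalization leaf delay (see
#' [cgm_constants()]); heading occurs
#' when post-sowing thermal time reaches `tt_em + (FLN + n_tail) * Phyl`,
#' never earlier than vernalization saturation. Sub-day resolution by linear
#' interpolation within the heading day.
#'
#' @param theta Named numeric vector or 1-row data frame with `VAI`, `SLDL`,
#'   `Phyl` (ordered as in `bounds` when unnamed).
#' @param env One row of the tibble from [build_environments()].
#' @param constants List from [cgm_constants()].
#' @param bounds Parameter bounds tibble (for column ordering/validation).
#' @return Heading time, real days after sowing.
#' @export
simulate_heading <- function(theta, env, constants = cgm_constants(),
                             bounds = default_bounds()) {
  if (!is.null(names(theta)) && all(bounds$parameter %in% names(theta))) {
    theta <- theta[bounds$parameter]
  }
  h <- heading_matrix(theta, env[1, ], constants, bounds)[1, 1]
  if (h < 0) {
    rlang::abort(
      sprintf("no heading within the %d-day horizon of %s (phase reached: %s)",
              env$horizon_days[1], env$env_id[1],
              no_heading_phase[[as.character(h)]]),
      class = "optimet_no_heading")
  }
  h
}

#' Simulate a phenotype table
#'
#' Observed heading dates are the crop-model output plus independent
#' centered Gaussian observation error:
#' \eqn{Y_{ijk} = f(\theta_i, E_j) + e_{ijk}}. The default error standard
#' deviation of 2 days mimics field scoring of heading.
#'
#' @param thetas Tibble with `genotype_id` and one column per parameter, or
#'   a matrix with rownames as genotype ids.
#' @param envs Environment tibble ([build_environments()]), possibly a
#'   subset (the trial design).
#' @param K Replications per environment (>= 1).
#' @param noise_sd Observation error standard deviation, days (>= 0).
#' @param seed Integer seed.
#' @param constants,bounds Passed to the phenology model.
#' @return A tibble `genotype_id`, `env_id`, `rep`, `heading_days`.
#' @export
simulate_phenotypes <- function(thetas, envs, K = 1L, noise_sd = 2,
                                seed = 1L, constants = cgm_constants(),
                                bounds = default_bounds()) {
  if (K < 1) stop_invalid("`K` must be >= 1")
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  if (is.data.frame(thetas)) {
    ids <- thetas$genotype_id
    th <- as.matrix(thetas[, bounds$parameter])
  } else {
    ids <- rownames(thetas)
    th <- thetas
  }
  f <- heading_matrix(th, envs, constants, bounds)
  if (any(f < 0)) {
    bad <- which(f < 0, arr.ind = TRUE)[1, ]
    rlang::abort(
      sprintf("no heading for genotype %s in environment %s (phase: %s)",
              ids[bad[1]], envs$env_id[bad[2]],
              no_heading_phase[[as.character(f[bad[1], bad[2]])]]),
      class = "optimet_no_heading")
  }
  set.seed(seed)
  out <- tidyr::expand_grid(gi = seq_along(ids), ej = seq_len(nrow(envs)),
                            rep = seq_len(K))
  tibble::tibble(
    genotype_id = ids[out$gi],
    env_id = envs$env_id[out$ej],
    rep = out$rep,
    heading_days = f[cbind(out$gi, out$ej)] +
      rnorm(nrow(out), sd = noise_sd)
  )
}
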