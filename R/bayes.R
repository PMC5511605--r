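#' Prior specification for the sampler
#'
#' Per-parameter uniform priors (the expert bounds) and an inverse-gamma
#' prior on the residual variance, in the shape-scale parameterization
#' (density proportional to \eqn{x^{-(a+1)} e^{-b/x}}; prior mean
#' b/(a-1)). Defaults: shape 4, scale 0.2 -- weakly informative, dominated
#' by the likelihood at realistic data sizes. With `heteroscedastic =
#' TRUE` one residual variance per environment is estimated, each under the
#' same inverse-gamma prior.
#'
#' @param bounds Bounds tibble ([default_bounds()]).
#' @param ig_shape,ig_scale Inverse-gamma shape a > 0 and scale b > 0.
#' @param heteroscedastic One residual variance per environment?
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(bounds = default_bounds(), ig_shape = 4,
                       ig_scale = 0.2, heteroscedastic = FALSE) {
  check_bounds(bounds)
  if (ig_shape <= 0 || ig_scale <= 0) {
    stop_invalid("inverse-gamma shape and scale must be > 0")
  }
  structure(list(bounds = bounds, ig_shape = ig_shape, ig_scale = ig_scale,
                 heteroscedastic = heteroscedastic),
            class = "prior_spec")
}

log_ig_density <- function(x, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}

#' Unnormalized log posterior of one variety's parameters
#'
#' Gaussian log-likelihood of the residuals (observed heading minus the
#' crop-model prediction) plus the log priors; `-Inf` outside the uniform
#' prior support. Intended for diagnostics and testing; the sampler uses a
#' vectorized equivalent internally.
#'
#' @param theta Parameter vector (ordered as the bounds, or named).
#' @param sigma2 Residual variance: scalar, or one value per row of `envs`
#'   in the heteroscedastic model.
#' @param obs Tibble of that variety's records: `env_id`, `heading_days`.
#' @param envs Environment tibble covering every `env_id` in `obs`.
#' @param priors `prior_spec` object.
#' @param constants Phenology constants.
#' @return A finite scalar inside the support, `-Inf` outside.
#' @export
log_posterior <- function(theta, sigma2, obs, envs,
                          priors = prior_spec(),
                          constants = cgm_constants()) {
  if (nrow(obs) == 0) stop_invalid("`obs` is empty")
  bounds <- priors$bounds
  if (!is.null(names(theta)) && all(bounds$parameter %in% names(theta))) {
    theta <- theta[bounds$parameter]
  }
  if (any(theta < bounds$lower) || any(theta > bounds$upper)) return(-Inf)
  ej <- match(obs$env_id, envs$env_id)
  if (anyNA(ej)) stop_invalid("`obs` references environments missing from `envs`")
  f <- heading_matrix(theta, envs, constants, bounds)[1, ]
  if (any(f[unique(ej)] < 0)) return(-Inf)
  s2 <- if (length(sigma2) == 1) rep(sigma2, nrow(envs)) else sigma2
  if (length(s2) != nrow(envs)) {
    stop_invalid("`sigma2` must be a scalar or one value per environment")
  }
  resid <- obs$heading_days - f[ej]
  ll <- sum(-0.5 * log(2 * pi * s2[ej]) - resid^2 / (2 * s2[ej]))
  lp_sigma <- sum(log_ig_density(unique(if (length(sigma2) == 1) sigma2 else s2),
                                 priors$ig_shape, priors$ig_scale))
  lp_theta <- -sum(log(bounds$upper - bounds$lower))
  ll + lp_sigma + lp_theta
}

# Per-variety Gaussian log-likelihood given a heading matrix f (I x Z),
# per-env variances s2 (length Z) and an observation index table.
variety_loglik <- function(f, s2, gi, ej, y, I) {
  fv <- f[cbind(gi, ej)]
  bad <- fv < 0
  resid2 <- (y - fv)^2
  term <- -0.5 * log(2 * pi * s2[ej]) - resid2 / (2 * s2[ej])
  term[bad] <- -Inf
  # every variety index 1..I is observed, so rowsum rows come back in order
  as.numeric(rowsum(term, gi, reorder = TRUE))
}

#' Block Metropolis-within-Gibbs sampler for the phenology model
#'
#' Estimates each variety's genetic parameters and the residual variance(s)
#' from a heading-date phenotype table. Each sweep updates, for every
#' variety in turn, its p = 3 coordinates jointly through a Gaussian
#' random-walk Metropolis step (varieties are conditionally independent
#' given the variance, so the proposals are evaluated in one vectorized
#' crop-model call), then the variance block: a random-walk on
#' \eqn{\log\sigma^2} with Jacobian correction by default, or a conjugate
#' inverse-gamma Gibbs draw (`sigma_update = "gibbs"`). Proposals start
#' diagonal at 2.5% of each prior range; during burn-in each variety's
#' proposal covariance adapts to the empirical covariance of its recent
#' draws (scaled 2.38^2/p, with a per-variety multiplier targeting a
#' 20-40% acceptance rate), then freezes so the retained chain is a valid
#' Markov chain. The covariance adaptation keeps proposals efficient along
#' the posterior's ridge directions, where the genetic parameters trade
#' off against each other.
#'
#' @param phenos Phenotype tibble (`genotype_id`, `env_id`, `rep`,
#'   `heading_days`).
#' @param envs Environment tibble covering every `env_id` in `phenos`.
#' @param priors `prior_spec` object.
#' @param n_iter Total sweeps (default 20000).
#' @param burn_in Discarded initial sweeps (default 1000).
#' @param proposal_frac Initial proposal sd as a fraction of each prior
#'   range.
#' @param sigma_update `"mh"` (log-scale random walk) or `"gibbs"`
#'   (conjugate draw; exact for the homoscedastic and heteroscedastic
#'   Gaussian model).
#' @param seed Integer seed; chains are bit-reproducible.
#' @param constants Phenology constants.
#' @return An object of class `optimet_chains`: `theta` array
#'   (iterations x varieties x parameters), `sigma2` matrix (iterations x
#'   n_variances), `burn_in`, `acceptance` tibble, ids and priors.
#' @export
run_mcmc <- function(phenos, envs, priors = prior_spec(),
                     n_iter = 20000L, burn_in = 1000L,
                     proposal_frac = 0.025,
                     sigma_update = c("mh", "gibbs"),
                     seed = 1L, constants = cgm_constants()) {
  sigma_update <- match.arg(sigma_update)
  if (n_iter <= burn_in) stop_invalid("`n_iter` must exceed `burn_in`")
  bounds <- priors$bounds
  p <- nrow(bounds)
  ids <- sort(unique(phenos$genotype_id))
  I <- length(ids)
  gi <- match(phenos$genotype_id, ids)
  ej <- match(phenos$env_id, envs$env_id)
  if (anyNA(ej)) stop_invalid("phenotypes reference environments missing from `envs`")
  y <- phenos$heading_days
  Z <- nrow(envs)
  n_var <- if (priors$heteroscedastic) Z else 1L
  n_obs_env <- tabulate(ej, Z)
  set.seed(seed)

  range_s <- bounds$upper - bounds$lower
  theta <- matrix(rep(bounds$lower + 0.5 * range_s, each = I), nrow = I)
  # nudge starts so identical varieties do not move in lockstep
  theta <- theta + matrix(rnorm(I * p, sd = 0.01), I, p) *
    rep(range_s, each = I)
  theta <- pmin(pmax(theta, rep(bounds$lower, each = I)),
                rep(bounds$upper, each = I))
  sigma2 <- rep(1, n_var)

  f_cur <- heading_matrix(theta, envs, constants, bounds)
  s2_env <- if (n_var == 1) rep(sigma2, Z) else sigma2
  ll_cur <- variety_loglik(f_cur, s2_env, gi, ej, y, I)
  if (any(!is.finite(ll_cur))) {
    # centre-of-support start fails for some variety: that is a data problem
    rlang::abort("initial parameter vector yields no heading for some variety",
                 class = "optimet_no_heading")
  }

  scale_theta <- rep(1, I)        # per-variety acceptance multiplier
  scale_sigma <- 0.5              # sd of the log-variance random walk
  # per-variety lower-triangular Cholesky factors of the proposal
  # covariance, stored as coordinate vectors for vectorized draws
  chol_l <- list(l11 = rep(proposal_frac * range_s[1], I),
                 l21 = numeric(I), l22 = rep(proposal_frac * range_s[2], I),
                 l31 = numeric(I), l32 = numeric(I),
                 l33 = rep(proposal_frac * range_s[3], I))
  jitter_cov <- diag((0.002 * range_s)^2, p)
  acc_theta <- numeric(I); acc_sigma <- 0
  win_theta <- numeric(I); win_sigma <- 0; win_n <- 0
  adapt_every <- 100L
  adapt_window <- 500L

  th_draws <- array(NA_real_, c(n_iter, I, p),
                    dimnames = list(NULL, ids, bounds$parameter))
  s2_draws <- matrix(NA_real_, n_iter, n_var)
  lower_m <- rep(bounds$lower, each = I)
  upper_m <- rep(bounds$upper, each = I)

  for (it in seq_len(n_iter)) {
    ## theta block (all varieties, conditionally independent)
    z <- matrix(rnorm(I * p), I, p)
    prop <- theta + scale_theta * cbind(
      z[, 1] * chol_l$l11,
      z[, 1] * chol_l$l21 + z[, 2] * chol_l$l22,
      z[, 1] * chol_l$l31 + z[, 2] * chol_l$l32 + z[, 3] * chol_l$l33)
    inb <- rowSums(prop < lower_m | prop > upper_m) == 0
    ll_prop <- rep(-Inf, I)
    log_u <- log(runif(I))
    if (any(inb)) {
      rows <- which(inb)
      keep_obs <- gi %in% rows
      sub_gi <- match(gi[keep_obs], rows)
      f_prop <- heading_matrix(prop[rows, , drop = FALSE], envs, constants,
                               bounds)
      ll_prop[rows] <- variety_loglik(f_prop, s2_env, sub_gi, ej[keep_obs],
                                      y[keep_obs], length(rows))
      acc <- log_u < (ll_prop - ll_cur)
      acc[!inb] <- FALSE
      if (any(acc)) {
        theta[acc, ] <- prop[acc, , drop = FALSE]
        f_cur[acc, ] <- f_prop[match(which(acc), rows), , drop = FALSE]
        ll_cur[acc] <- ll_prop[acc]
      }
      acc_theta <- acc_theta + acc
      win_theta <- win_theta + acc
    }

    ## variance block
    fv <- f_cur[cbind(gi, ej)]
    resid2 <- (y - fv)^2
    if (sigma_update == "gibbs") {
      if (n_var == 1) {
        sigma2 <- 1 / stats::rgamma(1, priors$ig_shape + length(y) / 2,
                                    priors$ig_scale + sum(resid2) / 2)
      } else {
        ss_env <- as.numeric(rowsum(resid2, ej, reorder = TRUE))
        present <- sort(unique(ej))
        ss <- numeric(Z); ss[present] <- ss_env
        sigma2 <- 1 / stats::rgamma(Z, priors$ig_shape + n_obs_env / 2,
                                    priors$ig_scale + ss / 2)
      }
      accepted_sigma <- TRUE
    } else {
      log_s2_prop <- log(sigma2) + rnorm(n_var, sd = scale_sigma)
      s2_prop <- exp(log_s2_prop)
      if (n_var == 1) {
        log_tgt <- function(s2) {
          -0.5 * length(y) * log(2 * pi * s2) - sum(resid2) / (2 * s2) +
            log_ig_density(s2, priors$ig_shape, priors$ig_scale) + log(s2)
        }
        accepted_sigma <- log(runif(1)) < (log_tgt(s2_prop) - log_tgt(sigma2))
        if (accepted_sigma) sigma2 <- s2_prop
      } else {
        ss_env <- numeric(Z)
        ss_tab <- rowsum(resid2, ej, reorder = TRUE)
        ss_env[sort(unique(ej))] <- as.numeric(ss_tab)
        log_tgt_j <- function(s2) {
          -0.5 * n_obs_env * log(2 * pi * s2) - ss_env / (2 * s2) +
            log_ig_density(s2, priors$ig_shape, priors$ig_scale) + log(s2)
        }
        acc_j <- log(runif(Z)) < (log_tgt_j(s2_prop) - log_tgt_j(sigma2))
        sigma2[acc_j] <- s2_prop[acc_j]
        accepted_sigma <- mean(acc_j)
      }
    }
    s2_env <- if (n_var == 1) rep(sigma2, Z) else sigma2
    ll_cur <- variety_loglik(f_cur, s2_env, gi, ej, y, I)
    acc_sigma <- acc_sigma + as.numeric(accepted_sigma)
    win_sigma <- win_sigma + as.numeric(accepted_sigma)
    win_n <- win_n + 1L

    th_draws[it, , ] <- theta
    s2_draws[it, ] <- sigma2

    ## adaptation (burn-in only; frozen afterwards so the chain is valid)
    if (it <= burn_in && it %% adapt_every == 0L) {
      rate <- win_theta / win_n
      scale_theta <- scale_theta * ifelse(rate > 0.4, 1.3,
                                          ifelse(rate < 0.2, 0.7, 1))
      # adapt each variety's proposal covariance to its recent draws
      win_idx <- seq.int(max(1L, it - adapt_window + 1L), it)
      for (i in seq_len(I)) {
        S <- stats::cov(th_draws[win_idx, i, , drop = TRUE]) * 2.38^2 / p +
          jitter_cov
        L <- t(chol(S))
        chol_l$l11[i] <- L[1, 1]
        chol_l$l21[i] <- L[2, 1]; chol_l$l22[i] <- L[2, 2]
        chol_l$l31[i] <- L[3, 1]; chol_l$l32[i] <- L[3, 2]
        chol_l$l33[i] <- L[3, 3]
      }
      rate_s <- win_sigma / win_n
      if (sigma_update == "mh") {
        scale_sigma <- scale_sigma * if (rate_s > 0.4) 1.3 else
          if (rate_s < 0.2) 0.7 else 1
      }
      win_theta[] <- 0; win_sigma <- 0; win_n <- 0L
    }
  }

  rate_theta <- acc_theta / n_iter
  if (any(rate_theta == 0)) {
    rlang::warn(sprintf(
      "no accepted parameter proposals for %d variety(ies) after adaptation",
      sum(rate_theta == 0)))
  }
  structure(list(
    theta = th_draws, sigma2 = s2_draws, burn_in = as.integer(burn_in),
    genotype_ids = ids, parameters = bounds$parameter, priors = priors,
    env_ids = envs$env_id, sigma_update = sigma_update,
    acceptance = tibble::tibble(
      block = c(ids, "sigma2"),
      rate = c(rate_theta, acc_sigma / n_iter))),
    class = "optimet_chains")
}

#' @export
print.optimet_chains <- function(x, ...) {
  cat(sprintf(
    "<optimet_chains> %d iterations (%d retained) x %d varieties x %d parameters; %d variance(s)\n",
    dim(x$theta)[1], dim(x$theta)[1] - x$burn_in, dim(x$theta)[2],
    dim(x$theta)[3], ncol(x$sigma2)))
  invisible(x)
}

retained_iterations <- function(chains) {
  seq.int(chains$burn_in + 1L, dim(chains$theta)[1])
}

#' Posterior mode of a scalar chain
#'
#' Mode of a Gaussian-kernel density estimate (Silverman's bandwidth,
#' 512-point grid) over the retained draws. When the prior support is
#' given, the draws are reflected at both bounds before smoothing so the
#' kernel does not leak mass outside the support (posteriors of bounded
#' parameters often pile up near a bound, where an uncorrected kernel
#' mode is biased inward). A numerically constant chain returns its value.
#'
#' @param draws Numeric vector of retained draws (>= 100).
#' @param support Optional `c(lower, upper)` prior support.
#' @return The abscissa of the density maximum.
#' @export
posterior_mode <- function(draws, support = NULL) {
  if (length(draws) < 100) stop_invalid("need >= 100 retained draws")
  if (sd(draws) == 0) return(draws[1])
  if (is.null(support)) {
    d <- density(draws, bw = "nrd0", n = 512)
    return(d$x[which.max(d$y)])
  }
  bw <- stats::bw.nrd0(draws)
  augmented <- c(draws, 2 * support[1] - draws, 2 * support[2] - draws)
  d <- density(augmented, bw = bw, n = 512, from = support[1],
               to = support[2])
  d$x[which.max(d$y)]
}

#' Posterior-mode estimates for every variety
#'
#' @param chains `optimet_chains` object.
#' @return A tibble with `genotype_id` and one column per parameter.
#' @export
posterior_estimates <- function(chains) {
  keep <- retained_iterations(chains)
  bounds <- chains$priors$bounds
  est <- vapply(seq_along(chains$parameters), function(s) {
    apply(chains$theta[keep, , s, drop = FALSE], 2, posterior_mode,
          support = c(bounds$lower[s], bounds$upper[s]))
  }, numeric(length(chains$genotype_ids)))
  est <- matrix(est, ncol = length(chains$parameters),
                dimnames = list(NULL, chains$parameters))
  dplyr::bind_cols(tibble::tibble(genotype_id = chains$genotype_ids),
                   tibble::as_tibble(est))
}

#' Tidy MCMC draws into a long tibble
#'
#' @param x `optimet_chains` object.
#' @param retained_only Drop burn-in iterations (default `TRUE`).
#' @param ... Unused.
#' @return Tibble `iteration`, `genotype_id`, `parameter`, `value`; the
#'   residual variance(s) appear under `genotype_id = NA` with parameter
#'   `"sigma2"` (suffixed by environment for heteroscedastic fits).
#' @export
tidy.optimet_chains <- function(x, retained_only = TRUE, ...) {
  its <- if (retained_only) retained_iterations(x) else
    seq_len(dim(x$theta)[1])
  th <- purrr::map_dfr(seq_along(x$parameters), function(s) {
    m <- x$theta[its, , s, drop = FALSE]
    tibble::tibble(
      iteration = rep(its, times = dim(m)[2]),
      genotype_id = rep(x$genotype_ids, each = length(its)),
      parameter = x$parameters[s],
      value = as.numeric(m))
  })
  s2_names <- if (ncol(x$sigma2) == 1) "sigma2" else
    paste0("sigma2_", x$env_ids)
  s2 <- purrr::map_dfr(seq_len(ncol(x$sigma2)), function(jj) {
    tibble::tibble(iteration = its, genotype_id = NA_character_,
                   parameter = s2_names[jj], value = x$sigma2[its, jj])
  })
  dplyr::bind_rows(th, s2)
}

#' One-row summary of an MCMC run
#'
#' @param x `optimet_chains` object.
#' @param ... Unused.
#' @return Tibble with iteration counts, mean block acceptance rates and
#'   the posterior-mean residual variance.
#' @export
glance.optimet_chains <- function(x, ...) {
  keep <- retained_iterations(x)
  tibble::tibble(
    n_iter = dim(x$theta)[1],
    n_retained = length(keep),
    n_varieties = dim(x$theta)[2],
    mean_theta_acceptance = mean(x$acceptance$rate[x$acceptance$block != "sigma2"]),
    sigma_acceptance = x$acceptance$rate[x$acceptance$block == "sigma2"],
    mean_sigma2 = mean(x$sigma2[keep, ]))
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
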