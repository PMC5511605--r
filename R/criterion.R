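#' Range-normalized distance between parameter vectors
#'
#' \eqn{\mathrm{dist}(\theta_u, \theta_v) =
#' [\sum_s ((\theta_{us} - \theta_{vs}) / (M_s - m_s))^2]^{1/2}}, with
#' \eqn{(m_s, M_s)} the prior bounds of parameter s. Normalization puts
#' parameters on different scales (e.g. VAI around 0.005 vs Phyl around
#' 100) on an equal footing.
#'
#' @param theta_u,theta_v Numeric vectors of length p.
#' @param bounds Bounds tibble ([default_bounds()]).
#' @return Non-negative scalar; 0 iff the vectors are equal.
#' @export
normalized_distance <- function(theta_u, theta_v, bounds = default_bounds()) {
  check_bounds(bounds)
  if (length(theta_u) != nrow(bounds) || length(theta_v) != nrow(bounds)) {
    stop_invalid("parameter vectors must match the bounds table")
  }
  r <- bounds$upper - bounds$lower
  sqrt(sum(((theta_u - theta_v) / r)^2))
}

#' A-priori parameter grid
#'
#' Discretizes each parameter interval into `g` regularly spaced values
#' (both endpoints included) and takes the Cartesian product: m = g^p rows
#' standing for the unknown distribution of parameter vectors across
#' varieties. Any user-supplied m x p matrix can replace it wherever a grid
#' is accepted (e.g. to encode an informative prior sample).
#'
#' @param bounds Bounds tibble.
#' @param g Levels per parameter (>= 2); 10 gives the default m = 1000.
#' @return A matrix with p named columns and g^p rows.
#' @export
build_grid <- function(bounds = default_bounds(), g = 10L) {
  check_bounds(bounds)
  if (g < 2) stop_invalid("`g` must be >= 2")
  levels <- purrr::map2(bounds$lower, bounds$upper, ~seq(.x, .y, length.out = g))
  names(levels) <- bounds$parameter
  as.matrix(tidyr::expand_grid(!!!levels))[, bounds$parameter, drop = FALSE]
}

# Pairwise range-normalized distance matrix of grid rows (m x m).
grid_distance_matrix <- function(grid, bounds = default_bounds()) {
  check_bounds(bounds)
  z <- sweep(grid, 2, bounds$lower) |>
    sweep(2, bounds$upper - bounds$lower, "/")
  sq <- rowSums(z^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(z)
  sqrt(pmax(d2, 0))
}

#' Noise-free model outputs for every grid row in every candidate
#'
#' Caches \eqn{f(\theta_u, E_j)} for all m grid rows and J candidate
#' environments; the criterion is then a cheap function of any design.
#' Grid rows for which the model does not reach heading in some candidate
#' environment are rejected: the a-priori grid must be simulable everywhere.
#'
#' @param grid m x p matrix from [build_grid()].
#' @param envs Candidate environment tibble.
#' @param constants,bounds Phenology model configuration.
#' @return An object of class `candidate_outputs`: list with `outputs`
#'   (m x J matrix), `env_ids`, `grid`, `bounds`.
#' @export
candidate_outputs <- function(grid, envs, constants = cgm_constants(),
                              bounds = default_bounds()) {
  out <- heading_matrix(grid, envs, constants, bounds)
  if (any(out < 0)) {
    bad <- which(out < 0, arr.ind = TRUE)
    stop_invalid(sprintf(
      "%d grid row/environment pairs never reach heading (first: row %d in %s); shrink the grid or extend the horizon",
      nrow(bad), bad[1, 1], envs$env_id[bad[1, 2]]))
  }
  colnames(out) <- envs$env_id
  structure(list(outputs = out, env_ids = envs$env_id, grid = grid,
                 bounds = bounds),
            class = "candidate_outputs")
}

#' @export
print.candidate_outputs <- function(x, ...) {
  cat(sprintf("<candidate_outputs> %d grid vectors x %d environments\n",
              nrow(x$outputs), ncol(x$outputs)))
  invisible(x)
}

check_design <- function(design, J) {
  idx <- design$indices
  if (length(idx) < 1 || anyDuplicated(idx) || any(idx < 1) || any(idx > J)) {
    stop_invalid("design indices must be distinct positions in 1..", J)
  }
  if (is.null(design$K) || design$K < 1) stop_invalid("`K` must be >= 1")
  design
}

#' Construct a design (a size-Z subset of the candidate list)
#'
#' @param indices Distinct integer positions into the candidate environment
#'   list.
#' @param K Replications per environment.
#' @return A list with class `met_design`.
#' @export
met_design <- function(indices, K = 1L) {
  structure(list(indices = as.integer(sort(indices)), K = as.integer(K)),
            class = "met_design")
}

#' @export
print.met_design <- function(x, ...) {
  cat(sprintf("<met_design> Z = %d, K = %d; indices: %s\n",
              length(x$indices), x$K, paste(x$indices, collapse = ", ")))
  invisible(x)
}

# Log-likelihood matrix: log L_uv = -(n_y/2) log(4 pi s2) - D2_uv / (4 s2),
# with D2_uv = K * sum_{j in design} (f(u,j) - f(v,j))^2.
log_likelihood_matrix <- function(outputs, design, sigma2_e) {
  if (sigma2_e <= 0) stop_invalid("`sigma2_e` must be > 0")
  design <- check_design(design, ncol(outputs$outputs))
  o <- outputs$outputs[, design$indices, drop = FALSE]
  sq <- rowSums(o^2)
  d2 <- design$K * pmax(outer(sq, sq, "+") - 2 * tcrossprod(o), 0)
  n_y <- length(design$indices) * design$K
  -(n_y / 2) * log(4 * pi * sigma2_e) - d2 / (4 * sigma2_e)
}

#' Likelihood matrix between a-priori parameter vectors under a design
#'
#' Element (u, v) is the likelihood of grid vector u given the noise-free
#' data generated by vector v on the design's environments:
#' \eqn{L_{uv} = (4\pi\sigma_e^2)^{-n_y/2}
#' \exp(-\Delta_{uv}'\Delta_{uv} / (4\sigma_e^2))}, with n_y = Z K
#' observations per variety and \eqn{\Delta_{uv}} the vector of output
#' differences over the design (each environment counted K times).
#' Computed in log space and exponentiated; prefer [weight_matrix()] for
#' anything downstream, as the raw likelihoods underflow for contrasted
#' designs.
#'
#' @param outputs `candidate_outputs` object.
#' @param design `met_design` object.
#' @param sigma2_e Residual variance assumed by the criterion (days^2).
#' @return A symmetric m x m matrix.
#' @export
likelihood_matrix <- function(outputs, design, sigma2_e = 4) {
  exp(log_likelihood_matrix(outputs, design, sigma2_e))
}

#' Column-stochastic weight matrix
#'
#' Normalizes the likelihood matrix by its column sums:
#' \eqn{W_{uv} = L_{uv} / \sum_u L_{uv}}. Column v weights every grid
#' vector u by how plausible u is given data generated by v. Accepts a raw
#' likelihood matrix or, preferably, its log (normalization is performed
#' with a per-column max shift so underflow cannot zero a column).
#'
#' @param L m x m likelihood matrix, or its elementwise log when
#'   `log = TRUE`.
#' @param log Is `L` on the log scale?
#' @return An m x m matrix with unit column sums.
#' @export
weight_matrix <- function(L, log = FALSE) {
  if (!log) {
    cs <- colSums(L)
    if (any(cs <= 0) || anyNA(cs)) {
      stop_invalid("a likelihood column underflowed to zero; use the log-space path (log = TRUE) or a larger sigma2_e")
    }
    return(sweep(L, 2, cs, "/"))
  }
  mx <- apply(L, 2, max)
  E <- exp(sweep(L, 2, mx))
  sweep(E, 2, colSums(E), "/")
}

#' Design criterion: expected normalized parameter distance under
#' likelihood weights
#'
#' \eqn{\sum_{u,v} \mathrm{dist}(\theta_u, \theta_v) W_{uv}}: the
#' likelihood-weighted average distance between a-priori parameter vectors
#' that the design fails to separate. Smaller is better; a design whose
#' outputs are far apart for far-apart parameter vectors concentrates the
#' weights near the diagonal where distances are zero.
#'
#' @param design `met_design` object.
#' @param outputs `candidate_outputs` object (carries the grid and bounds).
#' @param sigma2_e Residual variance assumed by the criterion (days^2);
#'   default 4 (2-day error standard deviation).
#' @param dist_mat Optional precomputed m x m distance matrix (from
#'   [grid_distance_matrix]); recomputed when `NULL`.
#' @return A non-negative scalar.
#' @export
optimet_value <- function(design, outputs, sigma2_e = 4, dist_mat = NULL) {
  if (is.null(dist_mat)) {
    dist_mat <- grid_distance_matrix(outputs$grid, outputs$bounds)
  }
  W <- weight_matrix(log_likelihood_matrix(outputs, design, sigma2_e),
                     log = TRUE)
  sum(dist_mat * W)
}

#' Criterion closure over a fixed candidate set
#'
#' Precomputes the grid distance matrix once and returns a function of a
#' design, which is what the search routines consume.
#'
#' @inheritParams optimet_value
#' @return A function `f(design) -> scalar`.
#' @export
optimet_criterion <- function(outputs, sigma2_e = 4) {
  dist_mat <- grid_distance_matrix(outputs$grid, outputs$bounds)
  o <- outputs$outputs
  force(sigma2_e)
  function(design) {
    design <- check_design(design, ncol(o))
    cpp_optimet_value(o[, design$indices, drop = FALSE], dist_mat,
                      design$K, sigma2_e)
  }
}
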