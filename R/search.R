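#' Exchange search for the criterion-optimal design
#'
#' Greedy stochastic descent: from a random initial Z-subset of the
#' candidates, each iteration proposes swapping one in-design environment
#' (uniform) with one out-of-design environment (uniform) and accepts the
#' swap only if the criterion strictly decreases (ties reject). Restarted
#' from several random initializations; the best final design across
#' restarts is returned, together with the per-restart traces of accepted
#' values.
#'
#' @param n_candidates Number of candidate environments J.
#' @param Z Design size (number of environments).
#' @param criterion_fn Function `f(met_design) -> scalar` to minimize (see
#'   [optimet_criterion()]).
#' @param K Replications per environment carried by the proposed designs.
#' @param n_iter Swap proposals per restart (default 3000).
#' @param n_restarts Independent random initializations (default 4).
#' @param seed Integer seed.
#' @return A list of class `exchange_result`: `design` (`met_design`),
#'   `value`, and `trace` tibble (`restart`, `iteration`, `value`) holding
#'   the non-increasing accepted-value path of every restart.
#' @export
exchange_search <- function(n_candidates, Z, criterion_fn, K = 1L,
                            n_iter = 3000L, n_restarts = 4L, seed = 1L) {
  if (Z > n_candidates) stop_invalid("`Z` cannot exceed the candidate count")
  if (n_iter < 1 || n_restarts < 1) stop_invalid("`n_iter` and `n_restarts` must be >= 1")
  set.seed(seed)
  eval_design <- function(idx) {
    v <- criterion_fn(met_design(idx, K))
    if (!is.finite(v)) {
      rlang::abort(paste0("criterion failed on design {",
                          paste(sort(idx), collapse = ", "), "}"),
                   class = "optimet_criterion_failure")
    }
    v
  }
  if (Z == n_candidates) {
    d <- met_design(seq_len(n_candidates), K)
    return(structure(list(design = d, value = eval_design(d$indices),
                          trace = tibble::tibble(restart = 1L, iteration = 0L,
                                                 value = eval_design(d$indices))),
                     class = "exchange_result"))
  }
  best_idx <- NULL
  best_val <- Inf
  traces <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    idx <- sample.int(n_candidates, Z)
    val <- eval_design(idx)
    tr_it <- integer(n_iter + 1); tr_val <- numeric(n_iter + 1)
    tr_it[1] <- 0L; tr_val[1] <- val
    k <- 1L
    outside <- setdiff(seq_len(n_candidates), idx)
    for (it in seq_len(n_iter)) {
      pos_in <- sample.int(Z, 1)
      pos_out <- sample.int(length(outside), 1)
      cand <- idx
      cand[pos_in] <- outside[pos_out]
      v <- eval_design(cand)
      if (v < val) {
        outside[pos_out] <- idx[pos_in]
        idx <- cand
        val <- v
        k <- k + 1L
        tr_it[k] <- it; tr_val[k] <- val
      }
    }
    traces[[r]] <- tibble::tibble(restart = r, iteration = tr_it[seq_len(k)],
                                  value = tr_val[seq_len(k)])
    if (val < best_val) {
      best_val <- val
      best_idx <- idx
    }
  }
  structure(list(design = met_design(best_idx, K), value = best_val,
                 trace = dplyr::bind_rows(traces)),
            class = "exchange_result")
}

#' @export
print.exchange_result <- function(x, ...) {
  cat(sprintf("<exchange_result> value = %.6g; Z = %d; indices: %s\n",
              x$value, length(x$design$indices),
              paste(x$design$indices, collapse = ", ")))
  invisible(x)
}

#' Exhaustive search over all Z-subsets
#'
#' Global minimizer by enumeration; usable as an oracle on small candidate
#' sets. Ties break deterministically toward the lexicographically smallest
#' index set.
#'
#' @inheritParams exchange_search
#' @param max_subsets Enumeration cap; exceeding it is an error suggesting
#'   [exchange_search()].
#' @return A list `design`, `value` of the global optimum.
#' @export
exhaustive_search <- function(n_candidates, Z, criterion_fn, K = 1L,
                              max_subsets = 1e5) {
  n_sub <- choose(n_candidates, Z)
  if (n_sub > max_subsets) {
    stop_invalid(sprintf(
      "C(%d, %d) = %.0f subsets exceeds the cap of %.0f; use exchange_search()",
      n_candidates, Z, n_sub, max_subsets))
  }
  subsets <- combn(n_candidates, Z)
  best_val <- Inf
  best_idx <- NULL
  for (s in seq_len(ncol(subsets))) {
    v <- criterion_fn(met_design(subsets[, s], K))
    if (v < best_val) {
      best_val <- v
      best_idx <- subsets[, s]
    }
  }
  list(design = met_design(best_idx, K), value = best_val)
}

reasoned_periods_default <- function() {
  list(october = 10L, early_winter = c(11L, 12L), late_winter = c(1L, 2L),
       spring = c(3L, 4L))
}

#' Sample comparison designs
#'
#' Baseline design samplers used to benchmark the optimized design:
#' * `"random"` — uniform Z-subsets of the candidates;
#' * `"composition"` — uniform subsets containing exactly `n_winter` winter
#'   sowings (and `Z - n_winter` spring sowings), the stratified random
#'   baseline;
#' * `"reasoned"` — subsets in which every sowing period is represented;
#'   with the default four periods (October; November/December;
#'   January/February; March/April) and Z = 4 each design covers each
#'   period exactly once.
#'
#' @param envs Candidate environment tibble (needs `sowing_date`).
#' @param Z Design size.
#' @param strategy `"random"`, `"composition"`, or `"reasoned"`.
#' @param n_samples Number of designs to draw.
#' @param K Replications carried by the designs.
#' @param n_winter For `"composition"`: required number of winter sowings.
#' @param periods For `"reasoned"`: named list mapping period name to
#'   sowing months.
#' @param winter_months Months classed as winter sowings.
#' @param seed Integer seed.
#' @return A list of `met_design` objects.
#' @export
sample_designs <- function(envs, Z, strategy = c("random", "composition",
                                                 "reasoned"),
                           n_samples = 10L, K = 1L, n_winter = NULL,
                           periods = reasoned_periods_default(),
                           winter_months = c(9L, 10L, 11L, 12L), seed = 1L) {
  strategy <- match.arg(strategy)
  J <- nrow(envs)
  if (Z > J) stop_invalid("`Z` cannot exceed the candidate count")
  set.seed(seed)
  month <- as.integer(format(as.Date(envs$sowing_date), "%m"))
  draw_one <- switch(
    strategy,
    random = function() sample.int(J, Z),
    composition = {
      if (is.null(n_winter) || n_winter < 0 || n_winter > Z) {
        stop_invalid("`n_winter` must be given in 0..Z for the composition strategy")
      }
      winter_pool <- which(month %in% winter_months)
      spring_pool <- setdiff(seq_len(J), winter_pool)
      if (length(winter_pool) < n_winter) {
        stop_invalid("not enough winter-sowing candidates (class 'winter' too small)")
      }
      if (length(spring_pool) < Z - n_winter) {
        stop_invalid("not enough spring-sowing candidates (class 'spring' too small)")
      }
      function() c(winter_pool[sample.int(length(winter_pool), n_winter)],
                   spring_pool[sample.int(length(spring_pool), Z - n_winter)])
    },
    reasoned = {
      pools <- purrr::map(periods, ~which(month %in% .x))
      empty <- names(pools)[purrr::map_int(pools, length) == 0]
      if (length(empty) > 0) {
        stop_invalid("no candidate environments in sowing period(s): ",
                     paste(empty, collapse = ", "))
      }
      if (Z < length(pools)) {
        stop_invalid("`Z` must be at least the number of sowing periods (",
                     length(pools), ")")
      }
      function() {
        base <- purrr::map_int(pools, ~.x[sample.int(length(.x), 1)])
        extra_pool <- setdiff(seq_len(J), base)
        extra <- if (Z > length(base)) extra_pool[sample.int(length(extra_pool), Z - length(base))] else integer()
        c(base, extra)
      }
    })
  purrr::map(seq_len(n_samples), ~met_design(draw_one(), K))
}
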