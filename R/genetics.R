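#' Simulate LD-structured inbred genotypes
#'
#' Haplotypes of fully inbred lines, coded 0/1, generated along a genetic
#' map by a two-state refresh chain: walking along each chromosome, the
#' allele is copied from the previous marker and refreshed with the
#' Haldane recombination fraction of `mosaic_depth` times the inter-marker
#' distance (a founder-mosaic accumulated over several meioses). This
#' yields linkage disequilibrium decaying with map distance: identical
#' alleles at coincident markers, near-independence beyond tens of cM.
#' Marker allele frequencies are drawn uniformly within
#' `founder_maf_range`; markers monomorphic in the sample are resampled at
#' a random line so none remain.
#'
#' @param n_lines Number of inbred lines.
#' @param n_chrom Chromosomes.
#' @param markers_per_chrom Markers per chromosome.
#' @param chrom_length_cM Chromosome map length (cM); markers are placed
#'   uniformly at random and sorted.
#' @param founder_maf_range Range of marker allele frequencies.
#' @param mosaic_depth Accumulated meioses scaling the map distance in the
#'   recombination fraction (default 8).
#' @param seed Integer seed.
#' @return A list of class `genotype_data`: `matrix` (n_lines x M, 0/1,
#'   dimnames set), `map` tibble (`marker_id`, `chrom`, `pos_cM`),
#'   `line_ids`, `marker_ids`.
#' @export
simulate_genotypes <- function(n_lines, n_chrom = 7L, markers_per_chrom = 150L,
                               chrom_length_cM = 150, founder_maf_range = c(0.2, 0.8),
                               mosaic_depth = 8, seed = 1L) {
  if (n_lines < 2 || n_chrom < 1 || markers_per_chrom < 2) {
    stop_invalid("need >= 2 lines and >= 2 markers per chromosome")
  }
  set.seed(seed)
  maps <- purrr::map_dfr(seq_len(n_chrom), function(cc) {
    pos <- sort(runif(markers_per_chrom, 0, chrom_length_cM))
    tibble::tibble(chrom = cc, pos_cM = pos)
  })
  maps$marker_id <- sprintf("m%d_%03d", maps$chrom,
                            stats::ave(maps$pos_cM, maps$chrom,
                                       FUN = seq_along))
  M <- nrow(maps)
  p_freq <- runif(M, founder_maf_range[1], founder_maf_range[2])
  X <- matrix(0L, n_lines, M)
  col0 <- 0L
  for (cc in seq_len(n_chrom)) {
    pos <- maps$pos_cM[maps$chrom == cc]
    nm <- length(pos)
    d <- diff(pos)
    # refresh probability: Haldane fraction of the mosaic-scaled distance
    r <- 0.5 * (1 - exp(-2 * mosaic_depth * d / 100))
    pj <- p_freq[col0 + seq_len(nm)]
    H <- matrix(0L, n_lines, nm)
    H[, 1] <- as.integer(runif(n_lines) < pj[1])
    for (j in 2:nm) {
      refresh <- runif(n_lines) < r[j - 1]
      H[, j] <- ifelse(refresh, as.integer(runif(n_lines) < pj[j]), H[, j - 1])
    }
    X[, col0 + seq_len(nm)] <- H
    col0 <- col0 + nm
  }
  # flip one allele at monomorphic markers so every marker segregates
  mono <- which(matrixStats_colVars(X) == 0)
  for (j in mono) {
    i <- sample.int(n_lines, 1)
    X[i, j] <- 1L - X[i, j]
  }
  line_ids <- sprintf("line%03d", seq_len(n_lines))
  dimnames(X) <- list(line_ids, maps$marker_id)
  structure(list(matrix = X, map = maps[, c("marker_id", "chrom", "pos_cM")],
                 line_ids = line_ids, marker_ids = maps$marker_id),
            class = "genotype_data")
}

# column variances without matrixStats
matrixStats_colVars <- function(X) {
  n <- nrow(X)
  (colSums(X^2) - colSums(X)^2 / n) / (n - 1)
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("<genotype_data> %d lines x %d markers on %d chromosome(s)\n",
              nrow(x$matrix), ncol(x$matrix), length(unique(x$map$chrom))))
  invisible(x)
}

#' Assign a QTL architecture to each genetic parameter
#'
#' For each parameter, samples `n_qtl` markers as QTL with effect sizes
#' following a geometric series (|effect| of the k-th QTL proportional to
#' `ratio^k`) and random signs; the per-line raw scores are affinely
#' rescaled so the population spans the central 90% of the prior range
#' (`[lower + 0.05 R, upper - 0.05 R]`). All QTL markers (across all
#' parameters) are then removed from the analysis genotype matrix, so
#' detection must work through linked markers.
#'
#' @param genos `genotype_data` object.
#' @param bounds Bounds tibble, one parameter per row.
#' @param n_qtl QTL per parameter (default 25).
#' @param ratio Geometric ratio of successive effect magnitudes (default
#'   0.90).
#' @param seed Integer seed.
#' @return A list of class `trait_architecture`: `values` tibble
#'   (`genotype_id` + one column per parameter), `qtl` tibble
#'   (`parameter`, `marker_id`, `chrom`, `pos_cM`, `effect`, `rank`),
#'   `genos` (the `genotype_data` with QTL columns removed), and
#'   `rescale` (per-parameter slope/offset applied to the raw scores).
#' @export
assign_qtl <- function(genos, bounds = default_bounds(), n_qtl = 25L,
                       ratio = 0.90, seed = 1L) {
  M <- ncol(genos$matrix)
  p <- nrow(bounds)
  if (M <= 3 * n_qtl) stop_invalid("need more than ", 3 * n_qtl, " markers")
  set.seed(seed)
  qtl_cols <- sample.int(M, p * n_qtl)
  per_par <- split(qtl_cols, rep(seq_len(p), each = n_qtl))
  vals <- matrix(NA_real_, nrow(genos$matrix), p,
                 dimnames = list(genos$line_ids, bounds$parameter))
  rescale <- tibble::tibble(parameter = bounds$parameter, slope = NA_real_,
                            offset = NA_real_)
  qtl_tabs <- vector("list", p)
  for (s in seq_len(p)) {
    cols <- per_par[[s]]
    eff <- ratio^seq_len(n_qtl) * sample(c(-1, 1), n_qtl, replace = TRUE)
    raw <- as.numeric(genos$matrix[, cols, drop = FALSE] %*% eff)
    tries <- 0
    while (max(raw) == min(raw)) { # degenerate: resample the signal markers
      tries <- tries + 1
      if (tries > 20) stop_invalid("could not find a polymorphic QTL set")
      cols <- sample(setdiff(seq_len(M), unlist(per_par[-s])), n_qtl)
      raw <- as.numeric(genos$matrix[, cols, drop = FALSE] %*% eff)
    }
    per_par[[s]] <- cols
    R <- bounds$upper[s] - bounds$lower[s]
    lo <- bounds$lower[s] + 0.05 * R
    hi <- bounds$upper[s] - 0.05 * R
    slope <- (hi - lo) / (max(raw) - min(raw))
    offset <- lo - slope * min(raw)
    vals[, s] <- offset + slope * raw
    rescale$slope[s] <- slope
    rescale$offset[s] <- offset
    mk <- genos$map[match(genos$marker_ids[cols], genos$map$marker_id), ]
    qtl_tabs[[s]] <- tibble::tibble(parameter = bounds$parameter[s],
                                    marker_id = genos$marker_ids[cols],
                                    chrom = mk$chrom, pos_cM = mk$pos_cM,
                                    effect = eff * slope,
                                    rank = seq_len(n_qtl))
  }
  drop_cols <- unique(unlist(per_par))
  kept <- setdiff(seq_len(M), drop_cols)
  pruned <- structure(list(
    matrix = genos$matrix[, kept, drop = FALSE],
    map = genos$map[match(genos$marker_ids[kept], genos$map$marker_id), ],
    line_ids = genos$line_ids,
    marker_ids = genos$marker_ids[kept]), class = "genotype_data")
  structure(list(
    values = dplyr::bind_cols(tibble::tibble(genotype_id = genos$line_ids),
                              tibble::as_tibble(vals)),
    qtl = dplyr::bind_rows(qtl_tabs),
    genos = pruned,
    rescale = rescale), class = "trait_architecture")
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat(sprintf(
    "<trait_architecture> %d parameters x %d QTL each; %d analysis markers remain\n",
    length(unique(x$qtl$parameter)), max(x$qtl$rank), ncol(x$genos$matrix)))
  invisible(x)
}

#' Marker-based kinship matrix
#'
#' Genomic relationship matrix
#' \eqn{G = (X - 2P)(X - 2P)^T / (2 \sum_l p_l (1 - p_l))}, with X the
#' 0/2-coded homozygote dosage matrix of the inbred lines and \eqn{p_l}
#' the observed allele frequencies. Symmetric and positive semi-definite;
#' for fully inbred lines the mean diagonal is about 1 + f.
#'
#' @param genos `genotype_data` object, or a 0/1 line-by-marker matrix.
#' @return An n x n matrix with line ids as dimnames.
#' @export
vanraden_kinship <- function(genos) {
  X <- if (inherits(genos, "genotype_data")) genos$matrix else genos
  X2 <- 2 * X # inbred 0/1 coded as homozygote dosages 0/2
  p_l <- colMeans(X2) / 2
  poly <- p_l > 0 & p_l < 1
  if (sum(poly) < 2) stop_invalid("need >= 2 polymorphic markers")
  X2 <- X2[, poly, drop = FALSE]
  p_l <- p_l[poly]
  W <- sweep(X2, 2, 2 * p_l)
  G <- tcrossprod(W) / (2 * sum(p_l * (1 - p_l)))
  dimnames(G) <- list(rownames(X), rownames(X))
  G
}

# REML for y = 1 mu + g + e, g ~ N(0, sg2 G), e ~ N(0, se2 I), profiled to
# a 1-D search over lambda = se2 / sg2 on the spectral decomposition of G.
reml_lambda <- function(y, G, lambda_range = c(1e-4, 1e4), tol = 1e-6) {
  n <- length(y)
  eg <- eigen(G, symmetric = TRUE)
  U <- eg$vectors
  d <- pmax(eg$values, 0)
  yt <- as.numeric(crossprod(U, y))
  ot <- as.numeric(crossprod(U, rep(1, n)))
  neg_restricted_ll <- function(log_lambda) {
    lambda <- exp(log_lambda)
    v <- d + lambda
    mu <- sum(ot * yt / v) / sum(ot^2 / v)
    r <- yt - mu * ot
    ss <- sum(r^2 / v)
    sg2 <- ss / (n - 1)
    0.5 * ((n - 1) * log(sg2) + sum(log(v)) + log(sum(ot^2 / v)) +
             (n - 1))
  }
  opt <- optimize(neg_restricted_ll, log(lambda_range), tol = tol)
  lambda <- exp(opt$minimum)
  v <- d + lambda
  mu <- sum(ot * yt / v) / sum(ot^2 / v)
  r <- yt - mu * ot
  sg2 <- sum(r^2 / v) / (n - 1)
  list(lambda = lambda, mu = mu, sigma2_g = sg2, sigma2_e = sg2 * lambda,
       eigen = eg)
}

#' G-BLUP genomic prediction
#'
#' Fits `y = mu + g + e` with `g ~ N(0, sigma_g^2 G)` on the training
#' lines (variance ratio by restricted-likelihood maximization via a 1-D
#' search on the spectral decomposition of the training kinship block) and
#' predicts the genetic values of the test lines as
#' `G[test, train] (G[train, train] + lambda I)^-1 (y - mu)` plus the
#' fitted mean.
#'
#' @param y_train Named numeric vector of training phenotypes (names =
#'   line ids), or unnamed in the order of `train_ids`.
#' @param G Kinship covering training and test lines.
#' @param train_ids,test_ids Line ids (must index rows of `G`).
#' @return Tibble `genotype_id`, `prediction` for the test lines.
#' @export
gblup_predict <- function(y_train, G, train_ids, test_ids) {
  if (!all(c(train_ids, test_ids) %in% rownames(G))) {
    stop_invalid("`G` must cover all training and test lines")
  }
  if (!is.null(names(y_train))) y_train <- y_train[train_ids]
  if (anyNA(y_train)) stop_invalid("training phenotypes are incomplete")
  if (sd(y_train) == 0) {
    return(tibble::tibble(genotype_id = test_ids,
                          prediction = rep(y_train[1], length(test_ids))))
  }
  Gtt <- G[train_ids, train_ids]
  fit <- reml_lambda(y_train, Gtt)
  A <- Gtt + fit$lambda * diag(length(train_ids))
  sol <- tryCatch(solve(A, y_train - fit$mu), error = function(e) {
    rlang::warn("near-singular mixed-model system; adding ridge jitter")
    solve(A + 1e-8 * diag(nrow(A)), y_train - fit$mu)
  })
  pred <- fit$mu + as.numeric(G[test_ids, train_ids, drop = FALSE] %*% sol)
  tibble::tibble(genotype_id = test_ids, prediction = pred)
}

#' Mixed-model association scan
#'
#' Tests each marker's fixed effect in `y = mu + x beta + u + e`,
#' `u ~ N(0, sigma_g^2 G)`, with a random polygenic effect and no
#' structure covariates. Variance components are estimated once under the
#' null model and reused for every marker (the population-parameters-
#' previously-determined scheme), so each marker test reduces to
#' generalized least squares in the whitened coordinates. Two-sided
#' p-values from the Wald chi-square statistic; constant markers get
#' p = 1 and are flagged.
#'
#' @param y Phenotype vector, one value per line of `genos`.
#' @param genos `genotype_data` object (or 0/1 matrix with a `map`
#'   attribute-free matrix; then supply `map`).
#' @param G Kinship matrix (defaults to [vanraden_kinship()] of `genos`).
#' @param map Optional map tibble when `genos` is a plain matrix.
#' @return Tibble `marker_id`, `chrom`, `pos_cM`, `beta`, `pvalue`,
#'   `constant`.
#' @export
mlm_scan <- function(y, genos, G = NULL, map = NULL) {
  X <- if (inherits(genos, "genotype_data")) genos$matrix else genos
  if (is.null(map) && inherits(genos, "genotype_data")) map <- genos$map
  if (length(y) != nrow(X)) stop_invalid("`y` must have one value per line")
  if (is.null(G)) G <- vanraden_kinship(genos)
  fit <- reml_lambda(y, G)
  U <- fit$eigen$vectors
  w <- 1 / sqrt(pmax(fit$eigen$values, 0) + fit$lambda) # whitening weights
  yt <- w * as.numeric(crossprod(U, y))
  ones_t <- w * as.numeric(crossprod(U, rep(1, length(y))))
  Xt <- w * crossprod(U, X)
  # per-marker GLS of yt on [ones_t, xt]: project out the intercept first
  o2 <- sum(ones_t^2)
  y_r <- yt - ones_t * sum(ones_t * yt) / o2
  X_r <- Xt - outer(ones_t, colSums(ones_t * Xt) / o2)
  xx <- colSums(X_r^2)
  constant <- xx < 1e-12
  beta <- ifelse(constant, NA_real_, colSums(X_r * yt) / xx)
  df <- length(y) - 2
  rss <- pmax(sum(y_r^2) - ifelse(constant, 0, beta^2 * xx), 0)
  se2 <- rss / df
  wald <- ifelse(constant, 0, beta^2 * xx / se2)
  pval <- ifelse(constant, 1, pchisq(wald, df = 1, lower.tail = FALSE))
  ord <- match(colnames(X), map$marker_id)
  tibble::tibble(marker_id = colnames(X),
                 chrom = map$chrom[ord], pos_cM = map$pos_cM[ord],
                 beta = beta, pvalue = pval, constant = constant)
}

#' QTL detection power from a scan
#'
#' A simulated QTL counts as detected when at least one tested marker on
#' the same chromosome within `window_cM` of it has a p-value below
#' `alpha` (default 0.05/25, the per-parameter Bonferroni threshold for 25
#' simulated QTL). QTL with no marker inside the window count as
#' undetected.
#'
#' @param scan Scan tibble from [mlm_scan()].
#' @param qtl Tibble with `chrom`, `pos_cM` of the simulated QTL (for one
#'   parameter).
#' @param window_cM Detection window (cM), default 1.
#' @param alpha Significance threshold, default `0.05 / 25`.
#' @return Fraction of QTL detected, in \[0, 1\].
#' @export
detection_power <- function(scan, qtl, window_cM = 1, alpha = 0.05 / 25) {
  if (nrow(qtl) == 0) stop_invalid("no QTL supplied")
  hits <- purrr::map_lgl(seq_len(nrow(qtl)), function(q) {
    near <- scan$chrom == qtl$chrom[q] &
      abs(scan$pos_cM - qtl$pos_cM[q]) < window_cM
    any(near & scan$pvalue < alpha)
  })
  mean(hits)
}
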