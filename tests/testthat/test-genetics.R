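test_that("synthetic genotypes carry map-decaying linkage disequilibrium", {
  # effectively coincident markers are in complete LD
  g0 <- simulate_genotypes(100, n_chrom = 1, markers_per_chrom = 10,
                           chrom_length_cM = 1e-6, seed = 2)
  C <- suppressWarnings(cor(g0$matrix))
  expect_true(all(abs(C[upper.tri(C)]) > 0.999, na.rm = TRUE))
  # distant markers are near-independent
  g <- simulate_genotypes(500, n_chrom = 1, markers_per_chrom = 120,
                          chrom_length_cM = 150, seed = 3)
  pos <- g$map$pos_cM
  far <- which(outer(pos, pos, function(a, b) abs(a - b)) > 50 &
                 upper.tri(diag(length(pos))), arr.ind = TRUE)
  far <- far[sample.int(nrow(far), 500), ]
  r2 <- sapply(seq_len(nrow(far)), function(k)
    cor(g$matrix[, far[k, 1]], g$matrix[, far[k, 2]])^2)
  expect_lt(mean(r2), 0.05)
  # near markers are correlated
  near <- which(outer(pos, pos, function(a, b) abs(a - b)) < 1 &
                  upper.tri(diag(length(pos))), arr.ind = TRUE)
  r2n <- sapply(seq_len(nrow(near)), function(k)
    cor(g$matrix[, near[k, 1]], g$matrix[, near[k, 2]])^2)
  expect_gt(mean(r2n), 0.5)
  # determinism and hygiene
  g2 <- simulate_genotypes(500, n_chrom = 1, markers_per_chrom = 120,
                           chrom_length_cM = 150, seed = 3)
  expect_identical(g$matrix, g2$matrix)
  expect_true(all(g$matrix %in% c(0L, 1L)))
  expect_true(all(apply(g$matrix, 2, var) > 0)) # no monomorphic markers
  expect_false(is.unsorted(g$map$pos_cM))
})

test_that("QTL architectures follow the geometric series and bounds", {
  arch <- fix_panel()
  b <- default_bounds()
  for (s in seq_len(3)) {
    par <- b$parameter[s]
    q <- dplyr::filter(arch$qtl, parameter == par) |> dplyr::arrange(rank)
    expect_equal(nrow(q), 25)
    # successive effect magnitudes shrink by the geometric ratio
    expect_equal(abs(q$effect[-25]) / abs(q$effect[-1]), rep(1 / 0.9, 24),
                 tolerance = 1e-9)
    vals <- arch$values[[par]]
    # rescaled to the central 90% of the prior range
    R <- b$upper[s] - b$lower[s]
    expect_equal(min(vals), b$lower[s] + 0.05 * R, tolerance = 1e-9)
    expect_equal(max(vals), b$upper[s] - 0.05 * R, tolerance = 1e-9)
  }
  # ratio 1 gives equal magnitudes
  g <- simulate_genotypes(50, 2, 40, 100, seed = 5)
  arch1 <- assign_qtl(g, ratio = 1, n_qtl = 10, seed = 6)
  expect_equal(length(unique(round(abs(arch1$qtl$effect[arch1$qtl$parameter ==
                                                          "VAI"]), 12))), 1)
  # QTL markers are removed from the analysis matrix
  expect_false(any(arch$qtl$marker_id %in% arch$genos$marker_ids))
  expect_equal(ncol(arch$genos$matrix), 5 * 60 - 75)
})

test_that("kinship matches the dosage formula and is PSD", {
  # 3 lines x 4 markers hand example via an independent loop
  X <- matrix(c(0, 1, 1, 0,
                1, 1, 0, 0,
                0, 0, 1, 1), 3, 4, byrow = TRUE,
              dimnames = list(c("l1", "l2", "l3"), paste0("m", 1:4)))
  G <- vanraden_kinship(X)
  X2 <- 2 * X
  p <- colMeans(X2) / 2
  W <- sweep(X2, 2, 2 * p)
  G_hand <- matrix(0, 3, 3)
  denom <- 2 * sum(p * (1 - p))
  for (i in 1:3) for (j in 1:3) {
    G_hand[i, j] <- sum(W[i, ] * W[j, ]) / denom
  }
  expect_equal(G, G_hand, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(G, t(G))
  # two identical lines: off-diagonal equals the diagonal
  Xdup <- rbind(X, l4 = X[1, ])
  Gd <- vanraden_kinship(Xdup)
  expect_equal(Gd["l1", "l4"], Gd["l1", "l1"])
  # a line with itself is the largest entry of its row
  arch <- fix_panel()
  Gp <- vanraden_kinship(arch$genos)
  expect_true(all(diag(Gp) >= apply(Gp - diag(diag(Gp)), 1, max)))
  # positive semi-definite; inbred diagonal averages near 1 + f
  expect_gt(min(eigen(Gp, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
  expect_gt(mean(diag(Gp)), 1)
  expect_error(vanraden_kinship(matrix(1L, 4, 3)),
               class = "optimet_invalid_argument")
})

test_that("G-BLUP matches a direct mixed-model-equation solve", {
  arch <- fix_panel()
  G <- vanraden_kinship(arch$genos)
  ids <- arch$genos$line_ids
  train <- ids[1:10]
  test <- ids[11:15]
  set.seed(20)
  y <- setNames(arch$values$Phyl[1:10] + rnorm(10, sd = 2), train)
  pred <- gblup_predict(y, G, train, test)
  # oracle: mixed-model equations with the same variance ratio
  fit <- optimet:::reml_lambda(unname(y), G[train, train])
  n <- length(train)
  Ginv <- solve(G[train, train] + 1e-10 * diag(n))
  lhs <- rbind(cbind(n, t(rep(1, n))),
               cbind(rep(1, n), diag(n) + fit$lambda * Ginv))
  rhs <- c(sum(y), unname(y))
  sol <- solve(lhs, rhs)
  u_train <- sol[-1]
  pred_mme <- sol[1] + as.numeric(G[test, train] %*% Ginv %*% u_train)
  expect_equal(pred$prediction, pred_mme, tolerance = 1e-6)
  # a constant training vector predicts the constant
  const <- gblup_predict(setNames(rep(5, 10), train), G, train, test)
  expect_true(all(const$prediction == 5))
})

test_that("G-BLUP recovers strong genetic signal and gains with data", {
  genos <- simulate_genotypes(220, 3, 60, 120, seed = 21)
  G <- vanraden_kinship(genos)
  ids <- genos$line_ids
  # heritability-one trait: y is a genetic value drawn from N(0, G)
  ev <- eigen(G, symmetric = TRUE)
  mean_acc <- function(n_train, seed) {
    set.seed(seed)
    g_true <- as.numeric(ev$vectors %*% (sqrt(pmax(ev$values, 0)) *
                                           rnorm(length(ids))))
    names(g_true) <- ids
    train <- sample(ids, n_train)
    test <- setdiff(ids, train)[1:20]
    p <- gblup_predict(g_true[train], G, train, test)
    cor(p$prediction, g_true[test])
  }
  # noise-free recovery on the training side
  set.seed(22)
  g_true <- as.numeric(ev$vectors %*% (sqrt(pmax(ev$values, 0)) *
                                         rnorm(length(ids))))
  names(g_true) <- ids
  tr <- ids[1:150]
  fit <- gblup_predict(g_true[tr], G, tr, tr)
  expect_gt(cor(fit$prediction, g_true[tr]), 0.98)
  # accuracy rises with training size (averaged over 10 architectures)
  accs <- sapply(c(50, 100, 200), function(n)
    mean(sapply(1:10, function(s) mean_acc(n, 100 + s))))
  expect_false(is.unsorted(accs))
})

test_that("the mixed-model scan is calibrated and powerful", {
  genos <- simulate_genotypes(200, 2, 100, 120, seed = 25)
  G <- vanraden_kinship(genos)
  # null phenotype: rejection rate near the nominal level
  set.seed(26)
  y_null <- rnorm(200)
  scan <- mlm_scan(y_null, genos, G = G)
  expect_equal(nrow(scan), 200)
  rej <- mean(scan$pvalue < 0.05)
  expect_gte(rej, 0.02); expect_lte(rej, 0.09)
  # null p-values are approximately uniform
  ks <- suppressWarnings(stats::ks.test(scan$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
  # an unlinked marker explaining ~30% of variance on 200 lines is found;
  # the kinship is built from the background markers only, so the
  # polygenic term cannot absorb the tested effect
  set.seed(27)
  gm_q <- genos$matrix
  gm_q[, 10] <- as.integer(runif(200) < 0.5)
  x <- gm_q[, 10]
  G_wo <- vanraden_kinship(gm_q[, -10])
  y_qtl <- x * sqrt(0.3 / var(x)) + rnorm(200, sd = sqrt(0.7))
  scan_q <- mlm_scan(y_qtl, gm_q, G = G_wo, map = genos$map)
  expect_lt(unname(scan_q$pvalue[10]), 1e-6)
  # with identity kinship the Wald statistic is the OLS t-squared
  scan_i <- mlm_scan(y_null, genos, G = diag(200))
  for (j in c(3, 57)) {
    ols <- summary(lm(y_null ~ genos$matrix[, j]))$coefficients
    t2 <- ols[2, "t value"]^2
    wald <- stats::qchisq(scan_i$pvalue[j], 1, lower.tail = FALSE)
    expect_equal(unname(wald), unname(t2), tolerance = 1e-6)
  }
  # constant markers are flagged with p = 1
  gm <- genos$matrix
  gm[, 1] <- 1L
  scan_c <- mlm_scan(y_null, gm, G = G, map = genos$map)
  expect_equal(unname(scan_c$pvalue[1]), 1)
  expect_true(scan_c$constant[1])
})

test_that("detection power counts QTL hit within the window", {
  scan <- tibble::tibble(marker_id = paste0("m", 1:6),
                         chrom = c(1, 1, 1, 2, 2, 2),
                         pos_cM = c(10, 20, 30, 10, 20, 30),
                         pvalue = c(1e-10, 0.5, 0.5, 1e-10, 0.5, 0.5))
  qtl4 <- tibble::tibble(chrom = c(1, 1, 2, 2),
                         pos_cM = c(10.5, 25, 10.2, 50))
  # hand enumeration: QTL 1 and 3 detectable, 2 (too far) and 4 (no marker
  # within 1 cM) not
  expect_equal(detection_power(scan, qtl4), 0.5)
  scan_ns <- dplyr::mutate(scan, pvalue = 0.5)
  expect_equal(detection_power(scan_ns, qtl4), 0)
  scan_all <- dplyr::mutate(scan, pvalue = 1e-10)
  qtl_on <- tibble::tibble(chrom = c(1, 2), pos_cM = c(20, 20))
  expect_equal(detection_power(scan_all, qtl_on), 1)
  # cross-chromosome proximity never counts
  qtl_wrong <- tibble::tibble(chrom = 3, pos_cM = 10)
  expect_equal(detection_power(scan_all, qtl_wrong), 0)
})
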