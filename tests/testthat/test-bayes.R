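informative_design_envs <- function() {
  envs <- fix_envs(10)
  envs[match(c("s07_2015-03-15", "s08_2015-11-15", "s10_2015-09-15",
               "s10_2015-03-15"), envs$env_id), ]
}

test_that("log posterior matches a direct density evaluation", {
  envs <- informative_design_envs()
  priors <- prior_spec()
  theta <- c(VAI = 0.004, SLDL = 0.5, Phyl = 100)
  # outside any uniform bound the posterior is -Inf
  expect_identical(log_posterior(c(VAI = 0.02, SLDL = 0.5, Phyl = 100), 4,
                                 tibble::tibble(env_id = envs$env_id[1],
                                                heading_days = 150),
                                 envs, priors), -Inf)
  expect_identical(log_posterior(c(VAI = 0.004, SLDL = 0.5, Phyl = 79), 4,
                                 tibble::tibble(env_id = envs$env_id[1],
                                                heading_days = 150),
                                 envs, priors), -Inf)
  # single exact observation at sigma2 = 1: likelihood term -log(2 pi)/2
  f1 <- simulate_heading(theta, envs[1, ])
  lp <- log_posterior(theta, 1, tibble::tibble(env_id = envs$env_id[1],
                                               heading_days = f1),
                      envs, priors)
  prior_terms <- -sum(log(priors$bounds$upper - priors$bounds$lower)) +
    optimet:::log_ig_density(1, 4, 0.2)
  expect_equal(lp - prior_terms, -0.5 * log(2 * pi), tolerance = 1e-10)
  # three observations against an independently coded density sum
  obs <- tibble::tibble(env_id = envs$env_id[c(1, 2, 2)],
                        heading_days = c(150, 170, 171))
  f <- sapply(1:2, function(j) simulate_heading(theta, envs[j, ]))
  by_hand <- sum(dnorm(obs$heading_days, f[c(1, 2, 2)], 2, log = TRUE)) +
    prior_terms + optimet:::log_ig_density(4, 4, 0.2) -
    optimet:::log_ig_density(1, 4, 0.2)
  expect_equal(log_posterior(theta, 4, obs, envs, priors), by_hand,
               tolerance = 1e-10)
  expect_error(log_posterior(theta, 4, tibble::tibble(env_id = character(),
                                                      heading_days = numeric()),
                             envs, priors),
               class = "optimet_invalid_argument")
})

test_that("the sampler retains the advertised draws and is reproducible", {
  envs <- informative_design_envs()
  th <- tibble::tibble(genotype_id = c("a", "b"), VAI = c(0.003, 0.007),
                       SLDL = c(0.3, 0.7), Phyl = c(90, 110))
  ph <- simulate_phenotypes(th, envs, noise_sd = 2, seed = 2)
  ch1 <- run_mcmc(ph, envs, n_iter = 600, burn_in = 100, seed = 5)
  ch2 <- run_mcmc(ph, envs, n_iter = 600, burn_in = 100, seed = 5)
  expect_identical(ch1$theta, ch2$theta)
  expect_identical(ch1$sigma2, ch2$sigma2)
  expect_equal(dim(ch1$theta), c(600, 2, 3))
  expect_equal(dim(ch1$theta)[1] - ch1$burn_in, 500)
  # 20,000 iterations minus the 1,000 burn-in retain 19,000 draws
  expect_equal(length(optimet:::retained_iterations(
    fake_chains(array(0, c(20000, 1, 3),
                      dimnames = list(NULL, "a", NULL)), 1000L))), 19000)
  expect_error(run_mcmc(ph, envs, n_iter = 100, burn_in = 100),
               class = "optimet_invalid_argument")
})

test_that("near-noiseless data pins the posterior mode on the truth", {
  envs <- informative_design_envs()
  set.seed(8)
  I <- 5
  th <- tibble::tibble(genotype_id = sprintf("g%d", 1:I),
                       VAI = runif(I, 0.002, 0.008),
                       SLDL = runif(I, 0.2, 0.8), Phyl = runif(I, 85, 115))
  ph <- simulate_phenotypes(th, envs, noise_sd = 0, seed = 3)
  ch <- run_mcmc(ph, envs, n_iter = 6000, burn_in = 1000, seed = 4)
  est <- posterior_estimates(ch)
  b <- default_bounds()
  for (s in seq_len(3)) {
    par <- b$parameter[s]
    rel <- abs(est[[par]] - th[[par]][match(est$genotype_id,
                                            th$genotype_id)]) /
      (b$upper[s] - b$lower[s])
    expect_true(all(rel <= 0.02),
                label = sprintf("%s modes within 2%% of truth", par))
  }
})

test_that("the residual variance posterior concentrates on the truth", {
  envs <- informative_design_envs()
  set.seed(9)
  I <- 10
  th <- tibble::tibble(genotype_id = sprintf("g%02d", 1:I),
                       VAI = runif(I, 0.002, 0.008),
                       SLDL = runif(I, 0.2, 0.8), Phyl = runif(I, 85, 115))
  ph <- simulate_phenotypes(th, envs, K = 5, noise_sd = 2, seed = 3) # 200 obs
  ch <- run_mcmc(ph, envs, n_iter = 3000, burn_in = 500, seed = 4)
  s2_hat <- mean(ch$sigma2[optimet:::retained_iterations(ch), 1])
  expect_gt(s2_hat, 4 / 1.5)
  expect_lt(s2_hat, 4 * 1.5)
})

test_that("heteroscedastic fits carry one variance per environment", {
  envs <- informative_design_envs()
  th <- tibble::tibble(genotype_id = c("a", "b", "c"),
                       VAI = c(0.003, 0.005, 0.007),
                       SLDL = c(0.3, 0.5, 0.7), Phyl = c(90, 100, 110))
  ph <- simulate_phenotypes(th, envs, K = 2, noise_sd = 2, seed = 2)
  ch <- run_mcmc(ph, envs, priors = prior_spec(heteroscedastic = TRUE),
                 n_iter = 400, burn_in = 100, seed = 5)
  expect_equal(ncol(ch$sigma2), nrow(envs))
  expect_true(all(ch$sigma2 > 0))
  td <- tidy(ch)
  expect_equal(sum(grepl("^sigma2_", unique(td$parameter))), nrow(envs))
})

test_that("the linearized model matches the conjugate answer", {
  # pin VAI and SLDL to a sliver so heading is affine in Phyl under
  # constant temperature: y = a + b Phyl + e with known a, b
  b <- tibble::tibble(parameter = c("VAI", "SLDL", "Phyl"),
                      lower = c(0.00999999, 0, 80),
                      upper = c(0.01, 1e-9, 120))
  env <- const_env(tmean = 20)
  cst <- cgm_constants()
  v <- cst$vbee + 0.01 * cst$vern_t_max
  a <- (cst$tt_em + cst$vern_leaf_frac * 20 / v) / 20
  slope <- (cst$l_base + cst$n_tail) / 20
  set.seed(12)
  phyl_true <- 104
  n <- 12
  y <- a + slope * phyl_true + rnorm(n, sd = 1.5)
  ph <- tibble::tibble(genotype_id = "v1", env_id = rep(env$env_id, n),
                       rep = seq_len(n), heading_days = y)
  ch <- run_mcmc(ph, env, priors = prior_spec(bounds = b),
                 n_iter = 20000, burn_in = 2000, sigma_update = "gibbs",
                 seed = 6)
  keep <- optimet:::retained_iterations(ch)
  draws <- ch$theta[keep, 1, 3]
  # analytic marginal: flat prior on [80, 120], inverse-gamma variance
  # integrated out; p(Phyl | y) ~ (b0 + SS(Phyl)/2)^-(a0 + n/2)
  grid <- seq(80, 120, length.out = 4001)
  logp <- sapply(grid, function(p) {
    -(4 + n / 2) * log(0.2 + sum((y - a - slope * p)^2) / 2)
  })
  w <- exp(logp - max(logp)); w <- w / sum(w)
  mean_an <- sum(grid * w)
  sd_an <- sqrt(sum(grid^2 * w) - mean_an^2)
  expect_equal(mean(draws), mean_an, tolerance = 0.05 * sd_an + 0.05)
  expect_equal(sd(draws), sd_an, tolerance = 0.15 * sd_an)
})

test_that("posterior mode estimation behaves on known samples", {
  expect_equal(posterior_mode(rep(3.5, 200)), 3.5)
  set.seed(10)
  x <- rnorm(20000, mean = 2, sd = 0.5)
  # kernel mode of a symmetric unimodal sample sits near the mean, up to
  # bandwidth-scale jitter (Silverman bw here is ~0.15 sd)
  expect_lt(abs(posterior_mode(x) - mean(x)), 0.2 * sd(x))
  # an 80/20 bimodal mixture yields the heavier mode
  mix <- c(rnorm(8000, 0, 0.2), rnorm(2000, 3, 0.2))
  expect_lt(abs(posterior_mode(mix) - 0), 0.2)
  expect_error(posterior_mode(rnorm(50)), class = "optimet_invalid_argument")
  # support restriction keeps the grid inside the prior
  expect_gte(posterior_mode(runif(500, 0, 1e-4), support = c(0, 0.01)), 0)
})

test_that("chains tidy into long format and glance into one row", {
  arr <- array(rnorm(200 * 2 * 3), c(200, 2, 3),
               dimnames = list(NULL, c("a", "b"), c("VAI", "SLDL", "Phyl")))
  ch <- fake_chains(arr, burn_in = 50L)
  td <- tidy(ch)
  expect_equal(nrow(td), 150 * 2 * 3 + 150)
  expect_setequal(unique(td$parameter), c("VAI", "SLDL", "Phyl", "sigma2"))
  g <- glance(ch)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_retained, 150)
})
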