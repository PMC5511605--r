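# Shared fixtures, memoized per test run. All data is generated in code;
# the "world" is a small synthetic trial network (10 temperate sites, four
# sowing dates, multi-year weather) reused across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

fix_sites <- function(n = 10) {
  memo(paste0("sites", n),
       sites_table(sprintf("s%02d", seq_len(n)),
                   seq(43, 50.5, length.out = n)))
}

fix_weather <- function(n = 10) {
  memo(paste0("weather", n),
       generate_synthetic_weather(fix_sites(n), 2008:2016, seed = 7))
}

# the standard four sowing dates of one cropping cycle (calendar year 2015)
fix_sow_dates <- function() {
  as.Date(c("2015-09-15", "2015-10-15", "2015-11-15", "2015-03-15"))
}

fix_envs <- function(n = 10) {
  memo(paste0("envs", n),
       build_environments(fix_sites(n), fix_sow_dates(), fix_weather(n)))
}

# constant-temperature environment at the equator: day length is exactly
# 12 h every day, which makes closed-form heading fully analytic
const_env <- function(tmean = 20, lat = 0, sowing = "2020-03-01",
                      horizon = 400) {
  sites <- sites_table("cst", lat)
  dates <- seq(as.Date(sowing) - 10, as.Date(sowing) + horizon + 10, by = "day")
  w <- tibble::tibble(site_id = "cst", date = dates, tmean_c = tmean)
  build_environments(sites, as.Date(sowing), w, horizon_days = horizon)
}

# independent closed-form oracle for heading under constant temperature
# and constant day length (kept free of the package's C++ path)
oracle_heading <- function(VAI, SLDL, Phyl, temp = 20, DL = 12,
                           cst = cgm_constants()) {
  t_em <- cst$tt_em / temp
  v <- cst$vbee + VAI * min(max(temp, cst$vern_t_min), cst$vern_t_max)
  t_sat <- t_em + 1 / v
  delay_tt <- cst$vern_leaf_frac * temp / v
  fln <- cst$l_base + delay_tt / Phyl + SLDL * max(0, cst$dl_sat - DL)
  max((cst$tt_em + (fln + cst$n_tail) * Phyl) / temp, t_sat)
}

# hand-constructed two-point candidate_outputs object for criterion math
toy_outputs <- function(o1 = 100, o2 = 102) {
  b <- default_bounds()
  structure(list(
    outputs = matrix(c(o1, o2), 2, 1, dimnames = list(NULL, "e1")),
    env_ids = "e1",
    grid = matrix(c(0, 0, 80, 0.01, 1, 120), 2, 3, byrow = TRUE,
                  dimnames = list(NULL, b$parameter)),
    bounds = b), class = "candidate_outputs")
}

# a small QTL-derived variety panel (the study's trait architecture)
fix_panel <- function() {
  memo("panel", {
    genos <- simulate_genotypes(100, 5, 60, 120, seed = 11)
    assign_qtl(genos, default_bounds(), seed = 13)
  })
}

# minimal chains object for evaluation-metric tests
fake_chains <- function(theta_array, burn_in = 0L,
                        parameters = c("VAI", "SLDL", "Phyl")) {
  ids <- dimnames(theta_array)[[2]]
  structure(list(
    theta = theta_array,
    sigma2 = matrix(1, dim(theta_array)[1], 1),
    burn_in = as.integer(burn_in),
    genotype_ids = ids, parameters = parameters,
    priors = prior_spec(), env_ids = "e1", sigma_update = "mh",
    acceptance = tibble::tibble(block = c(ids, "sigma2"),
                                rate = 0.3)), class = "optimet_chains")
}
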