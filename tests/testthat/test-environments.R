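test_that("day length matches astronomical expectations", {
  # equator stays near 12 h all year
  expect_true(all(abs(day_length(0, 1:365) - 12) < 0.2))
  # equinox is near 12 h at mid latitudes
  expect_lt(abs(day_length(45, 80) - 12), 0.3)
  # independent evaluation of the declination formula at midsummer
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + 172) / 365)
  expected <- (24 / pi) * acos(-tan(48.7 * pi / 180) * tan(decl))
  expect_equal(day_length(48.7, 172), expected, tolerance = 1e-12)
  # polar clamp keeps values inside [0, 24]
  dl <- day_length(89, 1:365)
  expect_true(all(dl >= 0 & dl <= 24))
  expect_true(any(dl == 0) && any(dl == 24))
})

test_that("day length is hemispherically symmetric", {
  for (phi in c(10, 35, 48.7, 66)) {
    d <- sample.int(365, 20)
    flip <- ((d + 182) %% 365) + 1 # half-year shift, 1-based
    expect_true(all(abs(day_length(phi, d) - day_length(-phi, flip)) < 0.3))
  }
})

test_that("day length rejects out-of-range inputs", {
  expect_error(day_length(91, 100), class = "optimet_invalid_argument")
  expect_error(day_length(45, 0), class = "optimet_invalid_argument")
  expect_error(day_length(45, 367), class = "optimet_invalid_argument")
})

test_that("average year reproduces per-day means", {
  mk <- function(yr, temp) {
    dates <- seq(as.Date(sprintf("%d-01-01", yr)),
                 as.Date(sprintf("%d-12-31", yr)), by = "day")
    tibble::tibble(site_id = "a", date = dates, tmean_c = temp)
  }
  # constant years: mean of equals, and identical years return the input
  two <- dplyr::bind_rows(mk(2001, 10), mk(2002, 10))
  expect_true(all(average_year(two)$tmean_c == 10))
  # 5 and 15 degree years average to 10
  expect_true(all(average_year(dplyr::bind_rows(mk(2001, 5),
                                                mk(2002, 15)))$tmean_c == 10))
  # sinusoid-plus-noise years against a brute-force per-day average
  set.seed(1)
  yrs <- purrr::map(2001:2012, function(yr) {
    w <- mk(yr, 0)
    doy <- as.integer(format(w$date, "%j"))
    w$tmean_c <- 10 - 8 * cos(2 * pi * doy / 365) + rnorm(nrow(w), sd = 2)
    w
  })
  all_w <- dplyr::bind_rows(yrs)
  avg <- average_year(all_w)
  brute <- tapply(all_w$tmean_c, format(all_w$date, "%m-%d"), mean)
  brute <- brute[names(brute) != "02-29"]
  expect_equal(avg$tmean_c, as.numeric(brute[format(avg$date, "%m-%d")]),
               tolerance = 1e-12)
  # leap day is dropped before averaging
  leap <- dplyr::bind_rows(mk(2003, 10), mk(2004, 10)) # 2004 has Feb 29
  expect_equal(nrow(average_year(leap)), 365)
})

test_that("average year names years with missing days", {
  mk <- function(yr) {
    dates <- seq(as.Date(sprintf("%d-01-01", yr)),
                 as.Date(sprintf("%d-12-31", yr)), by = "day")
    tibble::tibble(site_id = "a", date = dates, tmean_c = 10)
  }
  broken <- dplyr::bind_rows(mk(2001), mk(2002)[-(50:59), ])
  expect_error(average_year(broken), "2002.*10 days missing",
               class = "optimet_invalid_argument")
})

test_that("synthetic weather honors its configuration", {
  sites <- sites_table(c("n", "s"), c(50, 44))
  # zero noise: exact sinusoid with the minimum on the stated coldest day
  w0 <- generate_synthetic_weather(sites, 2010, noise_sd = 0, seed = 1)
  wn <- dplyr::filter(w0, site_id == "n")
  expect_equal(as.integer(format(wn$date[which.min(wn$tmean_c)], "%j")), 20)
  lat_mean <- function(id) mean(dplyr::filter(w0, site_id == id)$tmean_c)
  # latitude gradient: the southern site is warmer
  expect_gt(lat_mean("s"), lat_mean("n"))
  expect_equal(lat_mean("n"), 13.5 - 0.25 * (50 - 45), tolerance = 0.01)
  # determinism
  w1 <- generate_synthetic_weather(sites, 2010:2011, seed = 42)
  w2 <- generate_synthetic_weather(sites, 2010:2011, seed = 42)
  expect_identical(w1, w2)
  expect_error(generate_synthetic_weather(sites, 2010, noise_sd = -1),
               class = "optimet_invalid_argument")
})

test_that("synthetic weather noise has the configured autocorrelation", {
  sites <- sites_table("a", 46)
  w <- generate_synthetic_weather(sites, 2001:2010, noise_sd = 2.5,
                                  ar1_rho = 0.7, seed = 3)
  w0 <- generate_synthetic_weather(sites, 2001:2010, noise_sd = 0, seed = 3)
  resid <- w$tmean_c - w0$tmean_c
  # sample lag-1 autocorrelation against the configured rho
  r1 <- cor(resid[-1], resid[-length(resid)])
  expect_equal(r1, 0.7, tolerance = 0.05)
  expect_equal(sd(resid), 2.5, tolerance = 0.15)
})

test_that("environments are the full site-by-sowing-date cross", {
  sites <- fix_sites(10)
  weather <- fix_weather(10)
  envs <- fix_envs(10)
  expect_equal(nrow(envs), 10 * 4)
  expect_false(anyDuplicated(envs$env_id) > 0)
  # day-0 temperature equals the weather value on the sowing date
  e1 <- envs[1, ]
  w1 <- dplyr::filter(weather, site_id == e1$site_id, date == e1$sowing_date)
  expect_equal(e1$tmean_c[[1]][1], w1$tmean_c)
  expect_equal(length(e1$tmean_c[[1]]), e1$horizon_days + 1)
  expect_true(all(e1$daylength_h[[1]] >= 0 & e1$daylength_h[[1]] <= 24))
  # a 39-site, 4-date candidate table yields 156 environments
  sites39 <- sites_table(sprintf("x%02d", 1:39), seq(43, 51, length.out = 39))
  w39 <- generate_synthetic_weather(sites39, 2014:2016, noise_sd = 0, seed = 1)
  envs39 <- build_environments(sites39, fix_sow_dates(), w39,
                               horizon_days = 250)
  expect_equal(nrow(envs39), 156)
  # 7 sites x 2 dates x 2 years gives 28 independent environments
  sites7 <- sites_table(sprintf("v%d", 1:7), seq(44, 50, length.out = 7))
  w7 <- generate_synthetic_weather(sites7, 2010:2013, noise_sd = 0, seed = 1)
  envs28 <- dplyr::bind_rows(purrr::map(c(2010, 2011), function(yr) {
    build_environments(sites7,
                       as.Date(paste0(yr, c("-10-15", "-11-15"))), w7,
                       horizon_days = 250)
  }))
  expect_equal(nrow(envs28), 28)
})

test_that("insufficient weather coverage is reported with site and date", {
  sites <- sites_table("a", 46)
  w <- generate_synthetic_weather(sites, 2010, seed = 1)
  expect_error(build_environments(sites, as.Date("2010-09-15"), w),
               "a.*2010-09-15", class = "optimet_invalid_argument")
  expect_error(build_environments(sites, as.Date("2010-01-01"), w,
                                  horizon_days = 100),
               class = "optimet_invalid_argument") # horizon too short
})

test_that("sowing dates classify into winter and spring sowings", {
  expect_equal(sowing_season(as.Date(c("2015-09-15", "2015-12-01",
                                       "2015-03-15", "2015-05-01"))),
               c("winter", "winter", "spring", "spring"))
})
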