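#' Astronomical day length
#'
#' Sunrise-to-sunset day length from the standard agronomic
#' solar-declination formula: declination
#' \eqn{\delta = 23.45^\circ \sin(2\pi (284 + doy)/365)} and day length
#' \eqn{(24/\pi)\,\mathrm{arccos}(-\tan\phi \tan\delta)}, with the arccos
#' argument clamped to \[-1, 1\] so polar day and polar night return 24 h
#' and 0 h.
#'
#' @param latitude_deg Latitude in degrees, in \[-90, 90\]. Vectorised.
#' @param day_of_year Day of year, 1..366. Vectorised (recycled against
#'   `latitude_deg`).
#' @return Day length in hours, in \[0, 24\].
#' @examples
#' day_length(48.7, 172) # midsummer at a north-temperate latitude
#' day_length(0, 1:365)  # the equator stays close to 12 h year round
#' @export
day_length <- function(latitude_deg, day_of_year) {
  if (!is.numeric(latitude_deg) || anyNA(latitude_deg) ||
      any(abs(latitude_deg) > 90)) {
    stop_invalid("`latitude_deg` must be numeric in [-90, 90]")
  }
  if (!is.numeric(day_of_year) || anyNA(day_of_year) ||
      any(day_of_year < 1) || any(day_of_year > 366)) {
    stop_invalid("`day_of_year` must be in 1..366")
  }
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + day_of_year) / 365)
  phi <- latitude_deg * pi / 180
  x <- pmin(1, pmax(-1, -tan(phi) * tan(decl)))
  (24 / pi) * acos(x)
}

#' Candidate trial sites as a tibble
#'
#' Validates and normalises a site table (`site_id`, `name`, `latitude_deg`).
#'
#' @param site_id Character keys, unique.
#' @param name Free-text site names (defaults to `site_id`).
#' @param latitude_deg Latitudes in degrees.
#' @return A tibble with one row per site.
#' @export
sites_table <- function(site_id, latitude_deg, name = site_id) {
  if (anyDuplicated(site_id)) stop_invalid("`site_id` values must be unique")
  if (any(!is.finite(latitude_deg)) || any(abs(latitude_deg) > 90)) {
    stop_invalid("latitudes must be finite degrees in [-90, 90]")
  }
  tibble::tibble(site_id = as.character(site_id),
                 name = as.character(name),
                 latitude_deg = as.numeric(latitude_deg))
}

#' Synthetic multi-year daily weather
#'
#' Generates daily mean temperature for each site and year as a seasonal
#' sinusoid plus first-order autocorrelated (AR(1)) noise. The annual mean
#' decreases with latitude (`mean_base - mean_lat_slope * (lat - 45)`), the
#' coldest day falls on `coldest_doy`, and the noise has marginal standard
#' deviation `noise_sd` with lag-1 autocorrelation `ar1_rho`. This stands in
#' for multi-year weather-station records when scoring designs: only the
#' contrast between candidate environments matters to the criterion, not
#' meteorological realism.
#'
#' @param sites Tibble from [sites_table()].
#' @param years Integer vector of calendar years to generate.
#' @param mean_base Annual mean temperature at 45 deg latitude (deg C).
#' @param mean_lat_slope Cooling per degree of latitude above 45 (deg C).
#' @param amplitude Seasonal half-range (deg C).
#' @param coldest_doy Day of year of the seasonal minimum.
#' @param noise_sd Marginal standard deviation of the AR(1) noise (deg C);
#'   0 gives the exact sinusoid.
#' @param ar1_rho Lag-1 autocorrelation of the noise, in \[0, 1).
#' @param seed Integer seed; same seed, same output.
#' @return A tibble with columns `site_id`, `date`, `tmean_c` covering every
#'   day of every requested year.
#' @export
generate_synthetic_weather <- function(sites, years,
                                       mean_base = 13.5,
                                       mean_lat_slope = 0.25,
                                       amplitude = 8,
                                       coldest_doy = 20,
                                       noise_sd = 2.5,
                                       ar1_rho = 0.7,
                                       seed = 1L) {
  if (length(years) < 1) stop_invalid("need at least one year")
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  if (ar1_rho < 0 || ar1_rho >= 1) stop_invalid("`ar1_rho` must be in [0, 1)")
  set.seed(seed)
  purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    lat <- sites$latitude_deg[i]
    site_mean <- mean_base - mean_lat_slope * (lat - 45)
    purrr::map_dfr(sort(years), function(yr) {
      dates <- seq(as.Date(sprintf("%d-01-01", yr)),
                   as.Date(sprintf("%d-12-31", yr)), by = "day")
      doy <- as.integer(format(dates, "%j"))
      seasonal <- site_mean - amplitude * cos(2 * pi * (doy - coldest_doy) / 365)
      n <- length(dates)
      if (noise_sd > 0) {
        innov_sd <- noise_sd * sqrt(1 - ar1_rho^2)
        e <- numeric(n)
        e[1] <- rnorm(1, sd = noise_sd)
        innov <- rnorm(n - 1, sd = innov_sd)
        for (t in 2:n) e[t] <- ar1_rho * e[t - 1] + innov[t - 1]
      } else {
        e <- numeric(n)
      }
      tibble::tibble(site_id = sites$site_id[i], date = dates,
                     tmean_c = seasonal + e)
    })
  })
}

#' Average year of a multi-year weather series
#'
#' Collapses several years of daily temperature at one site into a single
#' virtual year whose value on each calendar day is the mean of that day
#' across years. Feb 29 is dropped before averaging so every year
#' contributes the same 365 (month, day) cells. This "average year" is the
#' climate proxy used to score candidate designs before the season exists.
#'
#' @param weather Tibble with columns `site_id`, `date`, `tmean_c` for one
#'   site, spanning two or more years with identical day-of-year coverage.
#' @param year_label Calendar year used to date the virtual series (must not
#'   be a leap year); purely cosmetic. Default 2001.
#' @return A tibble `site_id`, `date`, `tmean_c` with 365 rows.
#' @export
average_year <- function(weather, year_label = 2001L) {
  stopifnot(all(c("site_id", "date", "tmean_c") %in% names(weather)))
  if (length(unique(weather$site_id)) != 1) {
    stop_invalid("`average_year()` expects weather for a single site")
  }
  w <- weather |>
    dplyr::mutate(md = format(.data$date, "%m-%d"),
                  yr = as.integer(format(.data$date, "%Y"))) |>
    dplyr::filter(.data$md != "02-29")
  if (length(unique(w$yr)) < 2) stop_invalid("need at least two years")
  cov <- w |> dplyr::count(.data$yr)
  bad <- cov$yr[cov$n != 365]
  if (length(bad) > 0) {
    missing_days <- w |>
      dplyr::filter(.data$yr %in% bad) |>
      dplyr::group_by(.data$yr) |>
      dplyr::summarise(missing = 365 - dplyr::n(), .groups = "drop")
    stop_invalid("years with incomplete daily coverage: ",
                 paste(sprintf("%d (%d days missing)", missing_days$yr,
                               missing_days$missing), collapse = ", "))
  }
  out <- w |>
    dplyr::group_by(.data$md) |>
    dplyr::summarise(tmean_c = mean(.data$tmean_c), .groups = "drop") |>
    dplyr::arrange(.data$md)
  tibble::tibble(
    site_id = weather$site_id[1],
    date = as.Date(paste0(year_label, "-", out$md)),
    tmean_c = out$tmean_c
  )
}

#' Build candidate environments from sites, sowing dates and weather
#'
#' Forms the full cross of sites and sowing dates. Each environment carries
#' the daily mean temperature and astronomical day length for days 0 (the
#' sowing day) through `horizon_days` after sowing, re-indexed to days after
#' sowing. Weather must cover the whole window for every combination.
#'
#' @param sites Tibble from [sites_table()].
#' @param sowing_dates `Date` vector (or ISO-8601 strings).
#' @param weather Tibble `site_id`, `date`, `tmean_c` covering every site.
#' @param horizon_days Series length after sowing (days); at least 250.
#' @return A tibble with one row per environment: `env_id`, `site_id`,
#'   `latitude_deg`, `sowing_date`, `horizon_days`, and list-columns
#'   `tmean_c`, `daylength_h` of length `horizon_days + 1`.
#' @export
build_environments <- function(sites, sowing_dates, weather,
                               horizon_days = 400L) {
  if (horizon_days < 250) stop_invalid("`horizon_days` must be >= 250")
  sowing_dates <- as.Date(sowing_dates)
  if (anyNA(sowing_dates)) stop_invalid("unparseable sowing dates")
  wx <- split(weather, weather$site_id)
  combos <- tidyr::expand_grid(site_idx = seq_len(nrow(sites)),
                               sowing_date = sowing_dates)
  rows <- purrr::pmap(combos, function(site_idx, sowing_date) {
    sid <- sites$site_id[site_idx]
    lat <- sites$latitude_deg[site_idx]
    w <- wx[[sid]]
    if (is.null(w)) stop_invalid("no weather for site ", sid)
    wanted <- seq(sowing_date, sowing_date + horizon_days, by = "day")
    idx <- match(wanted, w$date)
    if (anyNA(idx)) {
      stop_invalid(sprintf(
        "weather for site %s does not cover sowing %s + %d days",
        sid, format(sowing_date), horizon_days))
    }
    doy <- as.integer(format(wanted, "%j"))
    tibble::tibble(
      env_id = sprintf("%s_%s", sid, format(sowing_date)),
      site_id = sid,
      latitude_deg = lat,
      sowing_date = sowing_date,
      horizon_days = as.integer(horizon_days),
      tmean_c = list(w$tmean_c[idx]),
      daylength_h = list(day_length(lat, doy))
    )
  })
  dplyr::bind_rows(rows)
}

#' Classify a sowing date as winter or spring sown
#'
#' Months September through December count as winter sowings, January
#' through May as spring sowings; the boundary months are configurable.
#'
#' @param sowing_date `Date` vector.
#' @param winter_months Months (integers) treated as winter sowings.
#' @return Character vector `"winter"` / `"spring"`.
#' @export
sowing_season <- function(sowing_date, winter_months = c(9L, 10L, 11L, 12L)) {
  m <- as.integer(format(as.Date(sowing_date), "%m"))
  ifelse(m %in% winter_months, "winter", "spring")
}

#' Named expert trial network fixture
#'
#' A small fixed network of the kind an agronomist would propose from
#' expert knowledge: three sites on a north-to-south (hence photoperiodic)
#' gradient, each with a mid-November sowing, plus an additional mid-March
#' spring sowing at the southernmost site intended to expose vernalization.
#' Coordinates are synthetic stand-ins for the historical stations.
#'
#' @return A tibble `site_id`, `name`, `latitude_deg`, `sowing_month_day`.
#' @export
expert_met_fixture <- function() {
  tibble::tibble(
    site_id = c("mons", "versailles", "clermont", "clermont"),
    name = c("Mons-en-Chaussee (synthetic)", "Versailles (synthetic)",
             "Clermont-Ferrand (synthetic)", "Clermont-Ferrand (synthetic)"),
    latitude_deg = c(49.9, 48.8, 45.8, 45.8),
    sowing_month_day = c("11-15", "11-15", "11-15", "03-15")
  )
}
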