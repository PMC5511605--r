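default_config <- function() {
  list(
    seed = 1L,
    sites = list(n_sites = 10L, lat_min = 43, lat_max = 50.5),
    climate = list(mean_base = 13.5, mean_lat_slope = 0.25, amplitude = 8,
                   coldest_doy = 20L, noise_sd = 2.5, ar1_rho = 0.7),
    years = list(n_avg_years = 12L, experiment_years = c(2013L, 2014L, 2015L)),
    sowing_month_days = c("09-15", "10-15", "11-15", "03-15"),
    horizon_days = 400L,
    population = list(n_cal = 60L, n_val = 120L),
    genome = list(n_chrom = 7L, markers_per_chrom = 150L,
                  chrom_length_cM = 150, maf_min = 0.2, maf_max = 0.8,
                  mosaic_depth = 8),
    qtl = list(n_qtl = 25L, ratio = 0.9),
    noise_sd = 2,
    criterion = list(grid_g = 10L, sigma2_e = 4),
    design = list(Z = 4L, K = 1L),
    search = list(n_iter = 3000L, n_restarts = 4L),
    designs = list(n_random = 10L, include_expert = TRUE),
    mcmc = list(n_iter = 20000L, burn_in = 1000L),
    detection = list(window_cM = 1, alpha = 0.05 / 25),
    validation = list(n_sites = 5L, sowing_month_days = c("10-15", "11-15"))
  )
}

merge_config <- function(defaults, user, path = character()) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    prefix <- if (length(path)) paste0(paste(path, collapse = "$"), "$") else ""
    stop_invalid("unknown config key(s): ",
                 paste0(prefix, unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]])) stop_invalid("config key '", k, "' must be a mapping")
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load, validate and write pipeline configurations
#'
#' `optimet_config()` merges user overrides (a nested list or a YAML file)
#' into the full default configuration; unknown keys are rejected by name
#' and basic schema constraints are checked exhaustively. An empty file or
#' `NULL` gives the full default configuration. `write_config()` round-trips
#' a configuration to YAML.
#'
#' @param overrides Named nested list of overrides, or `NULL`.
#' @param path YAML file of overrides (ignored when `overrides` given).
#' @return A validated configuration list of class `optimet_config`.
#' @export
optimet_config <- function(overrides = NULL, path = NULL) {
  if (is.null(overrides) && !is.null(path)) {
    if (!file.exists(path)) stop_invalid("config file not found: ", path)
    overrides <- yaml::read_yaml(path)
    if (is.null(overrides)) overrides <- list()
  }
  if (is.null(overrides)) overrides <- list()
  cfg <- merge_config(default_config(), overrides)
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$sites$n_sites >= 2, "sites$n_sites must be >= 2")
  chk(cfg$sites$lat_min < cfg$sites$lat_max, "sites latitude range is empty")
  chk(cfg$years$n_avg_years >= 2, "years$n_avg_years must be >= 2")
  chk(length(cfg$years$experiment_years) >= 1, "need >= 1 experiment year")
  chk(cfg$horizon_days >= 250, "horizon_days must be >= 250")
  chk(cfg$population$n_cal >= 2 && cfg$population$n_val >= 2,
      "population sizes must be >= 2")
  chk(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  chk(cfg$criterion$grid_g >= 2, "criterion$grid_g must be >= 2")
  chk(cfg$criterion$sigma2_e > 0, "criterion$sigma2_e must be > 0")
  chk(cfg$design$Z >= 1 && cfg$design$K >= 1, "design Z and K must be >= 1")
  chk(cfg$mcmc$n_iter > cfg$mcmc$burn_in,
      "mcmc$n_iter must exceed mcmc$burn_in")
  chk(cfg$detection$alpha > 0 && cfg$detection$alpha < 1,
      "detection$alpha must be in (0, 1)")
  chk(all(grepl("^\\d{2}-\\d{2}$", cfg$sowing_month_days)),
      "sowing_month_days must be 'MM-DD' strings")
  if (length(problems) > 0) {
    stop_invalid("invalid configuration:\n  - ",
                 paste(problems, collapse = "\n  - "))
  }
  structure(cfg, class = c("optimet_config", "list"))
}

#' @rdname optimet_config
#' @param config Configuration to write.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Tile an average year over consecutive calendar years so environments
# whose horizon crosses the year boundary can be built (Feb 29 filled from
# Feb 28).
tile_average_year <- function(avg, from_year, n_years = 2L) {
  md <- format(avg$date, "%m-%d")
  dates <- seq(as.Date(sprintf("%d-01-01", from_year)),
               as.Date(sprintf("%d-12-31", from_year + n_years - 1L)),
               by = "day")
  md_all <- format(dates, "%m-%d")
  idx <- match(md_all, md)
  idx[is.na(idx)] <- match("02-28", md)
  tibble::tibble(site_id = avg$site_id[1], date = dates,
                 tmean_c = avg$tmean_c[idx])
}

# Expert-style design from within the candidate list: a north-to-south
# latitude gradient of late-autumn sowings plus a spring sowing at the
# southernmost site (the vernalization probe).
expert_design <- function(envs, K = 1L,
                          winter_months = c(10L, 11L, 12L),
                          spring_months = c(2L, 3L, 4L)) {
  month <- as.integer(format(as.Date(envs$sowing_date), "%m"))
  winter <- which(month %in% winter_months)
  spring <- which(month %in% spring_months)
  if (length(winter) < 3 || length(spring) < 1) {
    stop_invalid("candidates lack the winter/spring sowings an expert design needs")
  }
  lat <- envs$latitude_deg[winter]
  ord <- winter[order(lat)]
  pick <- unique(c(ord[1], ord[ceiling(length(ord) / 2)],
                   ord[length(ord)]))
  south_spring <- spring[which.min(envs$latitude_deg[spring])]
  met_design(unique(c(pick, south_spring))[seq_len(min(4, length(unique(c(pick, south_spring)))))],
             K)
}

pipeline_log <- function(lines, verbose, log_path = NULL) {
  if (verbose) message(lines)
  if (!is.null(log_path)) cat(lines, "\n", file = log_path, append = TRUE)
}

#' Run the full design-benchmark pipeline
#'
#' End-to-end simulation benchmark of design strategies: synthetic weather
#' and candidate environments, LD-structured genotypes with geometric-series
#' QTL architectures for the three genetic parameters, a calibration/
#' validation split, design selection (criterion-optimal by exchange
#' search, expert-style, random), then per experiment year: phenotype
#' simulation on each design, Bayesian parameter estimation, NRMSE against
#' the simulated truth, QTL detection power from a mixed-model scan of the
#' estimates, G-BLUP prediction of the validation lines' parameters, and
#' heading-time prediction accuracy in held-out validation environments
#' (predicted parameters fed back through the crop model).
#'
#' @param config `optimet_config` object (or overrides list passed to
#'   [optimet_config()]).
#' @param out_dir Optional run directory; when given, weather, genotypes,
#'   designs, estimates and the report are written under it.
#' @param seed Overrides `config$seed` when non-`NULL`.
#' @param verbose Log stage progress.
#' @return An object of class `optimet_pipeline`: `report` (long metric
#'   tibble from [summarize_design_run()]), `designs`, `candidates`,
#'   `truth`, `config`, `timings`.
#' @export
run_pipeline <- function(config = optimet_config(), out_dir = NULL,
                         seed = NULL, verbose = FALSE) {
  if (!inherits(config, "optimet_config")) config <- optimet_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  base_seed <- as.integer(config$seed) %% 1000000L
  log_path <- NULL
  if (!is.null(out_dir)) {
    for (d in c("", "weather", "genotypes", "designs", "estimates")) {
      dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
    }
    log_path <- file.path(out_dir, "log.txt")
    cat("", file = log_path)
  }
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    s <- Sys.time()
    res <- force(expr)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    pipeline_log(sprintf("[%s] %.1fs", name, timings[[name]]), verbose,
                 log_path)
    res
  }

  ## --- weather and candidate environments -------------------------------
  sites <- sites_table(
    sprintf("site%02d", seq_len(config$sites$n_sites)),
    seq(config$sites$lat_min, config$sites$lat_max,
        length.out = config$sites$n_sites))
  exp_years <- sort(as.integer(config$years$experiment_years))
  avg_years <- seq(min(exp_years) - config$years$n_avg_years,
                   min(exp_years) - 1L)
  all_years <- c(avg_years, exp_years, max(exp_years) + 1L)
  weather <- stage("weather", do.call(generate_synthetic_weather, c(
    list(sites = sites, years = all_years, seed = base_seed + 11L),
    config$climate)))

  avg_weather <- stage("average_year", {
    dplyr::bind_rows(purrr::map(split(weather, weather$site_id), function(w) {
      tile_average_year(
        average_year(dplyr::filter(w, as.integer(format(.data$date, "%Y")) %in%
                                     avg_years)),
        from_year = min(exp_years), n_years = 2L)
    }))
  })
  sow_dates <- function(yr) as.Date(paste0(yr, "-", config$sowing_month_days))
  candidates <- stage("candidates", build_environments(
    sites, sow_dates(min(exp_years)), avg_weather,
    horizon_days = config$horizon_days))

  ## --- genotypes, QTL, calibration/validation split ---------------------
  n_lines <- config$population$n_cal + config$population$n_val
  genos <- stage("genotypes", simulate_genotypes(
    n_lines, config$genome$n_chrom, config$genome$markers_per_chrom,
    config$genome$chrom_length_cM,
    c(config$genome$maf_min, config$genome$maf_max),
    config$genome$mosaic_depth, seed = base_seed + 23L))
  bounds <- default_bounds()
  arch <- stage("qtl", assign_qtl(genos, bounds, config$qtl$n_qtl,
                                  config$qtl$ratio, seed = base_seed + 31L))
  set.seed(base_seed + 41L)
  cal_ids <- sort(sample(genos$line_ids, config$population$n_cal))
  val_ids <- setdiff(genos$line_ids, cal_ids)
  truth <- arch$values
  cal_truth <- dplyr::filter(truth, .data$genotype_id %in% cal_ids)
  val_truth <- dplyr::filter(truth, .data$genotype_id %in% val_ids)

  ## --- designs ----------------------------------------------------------
  grid <- build_grid(bounds, config$criterion$grid_g)
  outputs <- stage("candidate_outputs", candidate_outputs(grid, candidates))
  crit <- optimet_criterion(outputs, config$criterion$sigma2_e)
  opt <- stage("exchange_search", exchange_search(
    nrow(candidates), config$design$Z, crit, K = config$design$K,
    n_iter = config$search$n_iter, n_restarts = config$search$n_restarts,
    seed = base_seed + 53L))
  designs <- list(optimet = opt$design)
  if (isTRUE(config$designs$include_expert)) {
    designs$expert <- expert_design(candidates, K = config$design$K)
  }
  rnd <- sample_designs(candidates, config$design$Z, "random",
                        n_samples = config$designs$n_random,
                        K = config$design$K, seed = base_seed + 61L)
  names(rnd) <- sprintf("random%02d", seq_along(rnd))
  designs <- c(designs, rnd)
  strategy_of <- function(nm) sub("[0-9]+$", "", nm)

  ## --- per-year benchmark ----------------------------------------------
  G_all <- vanraden_kinship(arch$genos)
  cal_rows <- match(cal_ids, arch$genos$line_ids)
  cal_genos <- structure(list(
    matrix = arch$genos$matrix[cal_rows, , drop = FALSE],
    map = arch$genos$map, line_ids = cal_ids,
    marker_ids = arch$genos$marker_ids), class = "genotype_data")
  G_cal <- G_all[cal_ids, cal_ids]

  records <- list()
  for (yr in exp_years) {
    yr_envs <- build_environments(sites, sow_dates(yr), weather,
                                  horizon_days = config$horizon_days)
    val_sites <- sites[seq_len(min(config$validation$n_sites, nrow(sites))), ]
    val_envs <- build_environments(
      val_sites, as.Date(paste0(yr, "-", config$validation$sowing_month_days)),
      weather, horizon_days = config$horizon_days)
    val_truth_mat <- heading_matrix(
      as.matrix(val_truth[, bounds$parameter]), val_envs)
    for (nm in names(designs)) {
      des <- designs[[nm]]
      des_envs <- yr_envs[des$indices, ]
      phenos <- simulate_phenotypes(cal_truth, des_envs, K = des$K,
                                    noise_sd = config$noise_sd,
                                    seed = base_seed + 100L * yr %% 9973L +
                                      which(names(designs) == nm))
      chains <- run_mcmc(phenos, des_envs,
                         n_iter = config$mcmc$n_iter,
                         burn_in = config$mcmc$burn_in,
                         seed = base_seed + 71L)
      est <- posterior_estimates(chains)
      nr <- nrmse(est, cal_truth, bounds)
      rec <- nr |>
        dplyr::mutate(design_id = nm, strategy = strategy_of(nm),
                      year = yr, metric = "nrmse") |>
        dplyr::rename(value = "nrmse")
      pow <- purrr::map_dfr(bounds$parameter, function(par) {
        scan <- mlm_scan(est[[par]][match(cal_ids, est$genotype_id)],
                         cal_genos, G = G_cal)
        tibble::tibble(
          parameter = par, metric = "power",
          value = detection_power(
            scan, dplyr::filter(arch$qtl, .data$parameter == par),
            window_cM = config$detection$window_cM,
            alpha = config$detection$alpha))
      }) |>
        dplyr::mutate(design_id = nm, strategy = strategy_of(nm), year = yr)
      pred <- purrr::map(bounds$parameter, function(par) {
        gblup_predict(setNames(est[[par]], est$genotype_id), G_all,
                      cal_ids, val_ids)$prediction
      })
      names(pred) <- bounds$parameter
      acc <- purrr::imap_dfr(pred, function(v, par) {
        tibble::tibble(parameter = par, metric = "accuracy",
                       value = prediction_accuracy(
                         v, val_truth[[par]][match(val_ids,
                                                   val_truth$genotype_id)]))
      }) |>
        dplyr::mutate(design_id = nm, strategy = strategy_of(nm), year = yr)
      val_pred_theta <- as.matrix(tibble::as_tibble(pred))
      ok <- rowSums(val_pred_theta < rep(bounds$lower, each = nrow(val_pred_theta)) |
                      val_pred_theta > rep(bounds$upper, each = nrow(val_pred_theta))) == 0
      val_pred_theta <- pmin(pmax(val_pred_theta,
                                  rep(bounds$lower, each = nrow(val_pred_theta))),
                             rep(bounds$upper, each = nrow(val_pred_theta)))
      val_pred_mat <- heading_matrix(val_pred_theta, val_envs)
      usable <- val_pred_mat >= 0 & val_truth_mat >= 0
      ht <- tibble::tibble(
        parameter = "heading",
        metric = c("heading_accuracy", "heading_rmse"),
        value = c(prediction_accuracy(val_pred_mat[usable],
                                      val_truth_mat[usable]),
                  sqrt(mean((val_pred_mat[usable] - val_truth_mat[usable])^2))),
        design_id = nm, strategy = strategy_of(nm), year = yr)
      records <- c(records, list(rec, pow, acc, ht))
      if (!is.null(out_dir)) {
        readr::write_tsv(est, file.path(out_dir, "estimates",
                                        sprintf("%s_%d.tsv", nm, yr)))
      }
    }
    pipeline_log(sprintf("[year %d] done", yr), verbose, log_path)
  }
  report <- summarize_design_run(dplyr::bind_rows(records))

  if (!is.null(out_dir)) {
    write_weather_tsv(weather, file.path(out_dir, "weather", "weather.tsv"))
    readr::write_tsv(tibble::as_tibble(cbind(
      line_id = arch$genos$line_ids,
      as.data.frame(arch$genos$matrix))),
      file.path(out_dir, "genotypes", "genotypes.tsv"))
    readr::write_tsv(arch$genos$map, file.path(out_dir, "genotypes", "map.tsv"))
    readr::write_tsv(arch$qtl, file.path(out_dir, "genotypes", "qtl.tsv"))
    for (nm in names(designs)) {
      write_design_json(designs[[nm]], candidates$env_id,
                        file.path(out_dir, "designs", paste0(nm, ".json")))
    }
    readr::write_tsv(opt$trace, file.path(out_dir, "designs", "trace.tsv"))
    readr::write_tsv(report, file.path(out_dir, "report.tsv"))
  }
  pipeline_log(sprintf("[total] %.1fs",
                       as.numeric(difftime(Sys.time(), t0, units = "secs"))),
               verbose, log_path)
  structure(list(report = report, designs = designs, candidates = candidates,
                 truth = truth, cal_ids = cal_ids, val_ids = val_ids,
                 exchange = opt, config = config, timings = timings),
            class = "optimet_pipeline")
}

#' @export
print.optimet_pipeline <- function(x, ...) {
  cat(sprintf("<optimet_pipeline> %d designs x %d year(s); %d metric records\n",
              length(x$designs), length(unique(x$report$year)),
              nrow(x$report)))
  print(glance(x))
  invisible(x)
}

#' Tidy the pipeline report
#'
#' @param x `optimet_pipeline` object.
#' @param ... Unused.
#' @return The long metric tibble (`design_id`, `strategy`, `year`,
#'   `parameter`, `metric`, `value`, `strategy_mean`).
#' @export
tidy.optimet_pipeline <- function(x, ...) x$report

#' Strategy-level summary of a pipeline run
#'
#' @param x `optimet_pipeline` object.
#' @param ... Unused.
#' @return A wide tibble: one row per strategy, across-parameter mean of
#'   each metric averaged over designs and years.
#' @export
glance.optimet_pipeline <- function(x, ...) {
  x$report |>
    dplyr::filter(.data$parameter == "mean") |>
    dplyr::group_by(.data$strategy, .data$metric) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "value")
}
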