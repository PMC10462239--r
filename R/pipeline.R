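#' Validate and complete a pipeline configuration
#'
#' Fills defaults for every analysis setting and rejects unknown keys,
#' out-of-range values, and overlapping or out-of-span period definitions.
#' Defaults encode the study conventions: JJA summer, monthly completeness
#' at 7 days, summer completeness at 2 months, annual at 9 months, site
#' eligibility at 11 years, alpha 0.05, B = 1000 bootstrap replicates,
#' early/late periods 2000--2009 and 2010--2016, exposure probabilities
#' 5/25/50/75/95%, urban cutoff 400 people/km2.
#'
#' @param raw Named list of overrides (possibly empty).
#' @return An object of class `penalty_config` (a validated named list).
#' @examples
#' cfg <- validate_config(list(n_lat = 6, n_lon = 6, n_sites = 5))
#' @export
validate_config <- function(raw = list()) {
  defaults <- list(
    scenario = "smooth", seed = 1L,
    n_lat = 12L, n_lon = 12L, years = 2000:2016,
    summer_months = 6:8,
    min_days = 7L, min_months_summer = 2L, min_months_annual = 9L,
    min_years = 11L,
    alpha = 0.05, B = 1000L,
    period_early = 2000:2009, period_late = 2010:2016,
    probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
    urban_cutoff = 400,
    thresholds = NULL,          # named list(pm_jja=, pm_ann=, o3_jja=) or NULL to derive
    n_sites = 25L, sampling_interval_days = 3L, miss_rate = 0.1,
    n_clusters = 3L,
    out_dir = NULL
  )
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, raw, keep.null = TRUE)
  chk <- function(ok, msg) if (!ok) stop("config: ", msg)
  chk(cfg$min_days >= 1, "`min_days` must be >= 1")
  chk(cfg$min_months_summer >= 1, "`min_months_summer` must be >= 1")
  chk(cfg$min_months_annual >= 1, "`min_months_annual` must be >= 1")
  chk(cfg$min_years >= 1, "`min_years` must be >= 1")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "`alpha` must be in (0, 1)")
  chk(cfg$B >= 1, "`B` must be >= 1")
  chk(all(cfg$probs > 0 & cfg$probs < 1), "`probs` must lie in (0, 1)")
  chk(cfg$urban_cutoff > 0, "`urban_cutoff` must be positive")
  chk(cfg$miss_rate >= 0 && cfg$miss_rate < 1, "`miss_rate` must be in [0, 1)")
  chk(length(intersect(cfg$period_early, cfg$period_late)) == 0,
      "periods must be disjoint")
  chk(all(c(cfg$period_early, cfg$period_late) %in% cfg$years),
      "periods must lie within the simulated years")
  if (!is.null(cfg$thresholds)) {
    chk(all(unlist(cfg$thresholds) > 0), "thresholds must be positive")
  }
  structure(cfg, class = "penalty_config")
}

#' Run the full climate-penalty pipeline on a synthetic scenario
#'
#' Orchestrates simulate -> aggregate -> estimate -> regional -> exposure
#' -> species on the configured synthetic scenario, writes every tabular
#' result as CSV under `out_dir` (when set), and returns a run report.
#' Identical configuration and seed give identical outputs.
#'
#' @param config A [validate_config()] result (or a raw list passed to it).
#' @return An object of class `penalty_run`: list with `config`, `counts`
#'   (per-stage record and attrition bookkeeping), and `results` (named
#'   list of result tibbles: `maps`, `regional`, `changes`, `exposure`,
#'   `species`, `stations`, `eligibility`).
#' @export
run_pipeline <- function(config = validate_config()) {
  if (!inherits(config, "penalty_config")) config <- validate_config(config)
  cfg <- config
  counts <- list()
  note <- function(stage, n_in, n_dropped, n_out) {
    counts[[length(counts) + 1]] <<- tibble::tibble(
      stage = stage, n_in = n_in, n_dropped = n_dropped, n_out = n_out)
  }

  # -- simulate ------------------------------------------------------------
  truth <- make_truth(cfg$seed, n_lat = cfg$n_lat, n_lon = cfg$n_lon,
                      years = cfg$years, scenario = cfg$scenario)
  sim <- simulate_fields(truth, frequency = "daily", include_species = TRUE)
  stations <- sample_stations(sim$pollutant, pm25, grid = truth$grid,
                              n_sites = cfg$n_sites,
                              sampling_interval_days = cfg$sampling_interval_days,
                              miss_rate = cfg$miss_rate, seed = cfg$seed + 10L)
  pop <- simulate_population(truth, n_clusters = cfg$n_clusters,
                             seed = cfg$seed)
  mask <- make_region_mask(truth)
  note("simulate", nrow(sim$pollutant) + nrow(stations), 0L,
       nrow(sim$pollutant) + nrow(stations))

  # -- aggregate -----------------------------------------------------------
  temp_daily <- daily_mean_temperature(sim$temperature, unit = cell_id)
  seas <- list(
    temp = summer_mean(monthly_mean(temp_daily, tmean, min_days = cfg$min_days),
                       min_months = cfg$min_months_summer,
                       months = cfg$summer_months),
    pm_jja = summer_mean(monthly_mean(sim$pollutant, pm25, min_days = cfg$min_days),
                         min_months = cfg$min_months_summer,
                         months = cfg$summer_months),
    pm_ann = annual_mean_jun_may(monthly_mean(sim$pollutant, pm25,
                                              min_days = cfg$min_days),
                                 min_months = cfg$min_months_annual),
    o3_jja = summer_mean(monthly_mean(sim$pollutant, o3, min_days = cfg$min_days),
                         min_months = cfg$min_months_summer,
                         months = cfg$summer_months)
  )
  st_monthly <- monthly_mean(stations, value, unit = site_id,
                             min_days = cfg$min_days)
  st_summer <- summer_mean(st_monthly, min_months = cfg$min_months_summer,
                           months = cfg$summer_months)
  eligibility <- site_eligibility(st_summer, min_years = cfg$min_years,
                                  years = cfg$years)
  note("aggregate", nrow(st_monthly),
       nrow(st_monthly) - sum(st_monthly$complete), sum(st_monthly$complete))

  # -- estimate ------------------------------------------------------------
  joined <- function(val_tbl) {
    dplyr::inner_join(
      dplyr::select(dplyr::filter(seas$temp, .data$complete),
                    "unit_id", "year", temp = "value"),
      dplyr::select(dplyr::filter(val_tbl, .data$complete),
                    "unit_id", "year", value = "value"),
      by = c("unit_id", "year"))
  }
  vars <- c(pm_jja = "pm_jja", pm_ann = "pm_ann", o3_jja = "o3_jja")
  maps <- purrr::imap(vars, function(v, nm) {
    gridwise_sensitivity(joined(seas[[v]]), value = value, temp = temp,
                         unit = unit_id, alpha = cfg$alpha,
                         coords = truth$grid, window = nm, variable = nm)
  })
  note("estimate", nrow(truth$grid),
       sum(is.na(maps$pm_jja$slope)), sum(!is.na(maps$pm_jja$slope)))

  # -- regional ------------------------------------------------------------
  regions <- levels(mask$region)
  regional <- purrr::map_dfr(names(vars), function(nm) {
    dat <- joined(seas[[nm]])
    purrr::map_dfr(regions, function(rg) {
      full <- bootstrap_regional(
        pool_region_anomalies(anomaly_pairs(dat, temp = temp, value = value,
                                            unit = unit_id),
                              mask, rg),
        B = cfg$B, seed = cfg$seed + 20L, region = rg, window = nm)
      tibble::tibble(region = rg, window = nm, period = "full",
                     slope = full$slope, se = full$se,
                     ci_lower = full$ci[1], ci_upper = full$ci[2],
                     n_points = full$n_points)
    })
  })
  changes <- purrr::map_dfr(names(vars), function(nm) {
    dat <- joined(seas[[nm]])
    purrr::map_dfr(regions, function(rg) {
      fit_p <- function(period) {
        bootstrap_regional(
          pool_region_anomalies(anomaly_pairs(dat, temp = temp, value = value,
                                              unit = unit_id, period = period),
                                mask, rg),
          B = cfg$B, seed = cfg$seed + 21L, region = rg, window = nm)
      }
      period_change(fit_p(cfg$period_early), fit_p(cfg$period_late))
    })
  })
  note("regional", nrow(regional) + nrow(changes), 0L,
       nrow(regional) + nrow(changes))

  # -- exposure ------------------------------------------------------------
  exposure <- purrr::map_dfr(names(vars), function(nm) {
    prepared <- align_population(pop, prepare_exposure_map(maps[[nm]]))
    thr <- cfg$thresholds[[nm]] %||% derive_threshold(prepared, tail = 0.25)
    dplyr::bind_rows(
      exposure_distribution(prepared, "population", probs = cfg$probs,
                            threshold = thr, window = nm, period = "full"),
      exposure_distribution(prepared, "area", probs = cfg$probs,
                            threshold = thr, window = nm, period = "full")
    )
  })
  urb <- urban_mask(pop, cutoff = cfg$urban_cutoff)
  strat <- stratified_sensitivity(
    anomaly_pairs(joined(seas$o3_jja), temp = temp, value = value,
                  unit = unit_id),
    urb, alpha = cfg$alpha)
  note("exposure", nrow(exposure), 0L, nrow(exposure))

  # -- species -------------------------------------------------------------
  sp_monthly <- sim$species |>
    tidyr::pivot_longer(cols = -c("cell_id", "date"), names_to = "species",
                        values_to = "conc") |>
    dplyr::filter(.data$species != "other") |>
    dplyr::mutate(conc = dplyr::if_else(.data$species == "oc",
                                        oc_to_oa(.data$conc), .data$conc),
                  species = dplyr::if_else(.data$species == "oc", "oa",
                                           .data$species))
  sp_seasonal <- sp_monthly |>
    dplyr::group_by(.data$species) |>
    dplyr::group_modify(function(d, key) {
      summer_mean(monthly_mean(d, conc, min_days = cfg$min_days),
                  min_months = cfg$min_months_summer,
                  months = cfg$summer_months)
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$complete) |>
    dplyr::inner_join(dplyr::select(dplyr::filter(seas$temp, .data$complete),
                                    "unit_id", "year", temp = "value"),
                      by = c("unit_id", "year"))
  species_sens <- component_sensitivity(sp_seasonal, value = value,
                                        temp = temp, unit = unit_id,
                                        alpha = cfg$alpha)
  species_sens <- contribution_fractions(species_sens)
  note("species", nrow(species_sens), 0L, nrow(species_sens))

  results <- list(maps = maps, regional = regional, changes = changes,
                  exposure = exposure, stratified = strat,
                  species = species_sens, stations = stations,
                  eligibility = eligibility, truth = truth)
  counts <- dplyr::bind_rows(counts)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, nm) readr::write_csv(x, file.path(cfg$out_dir,
                                                        paste0(nm, ".csv")))
    purrr::iwalk(maps, function(m, nm) wr(m, paste0("map_", nm)))
    wr(regional, "regional"); wr(changes, "period_changes")
    wr(exposure, "exposure"); wr(strat, "urban_stratified")
    wr(species_sens, "species"); wr(counts, "run_counts")
    write_stations_csv(stations, file.path(cfg$out_dir, "stations.csv"))
  }

  structure(list(config = cfg, counts = counts, results = results,
                 version = as.character(utils::packageVersion("climpen")),
                 seed = cfg$seed),
            class = "penalty_run")
}

#' @export
print.penalty_run <- function(x, ...) {
  cat("<penalty_run> scenario:", x$config$scenario,
      "| seed:", x$seed, "| climpen", x$version, "\n")
  print(x$counts)
  cat("\nRegional sensitivities (full record):\n")
  print(x$results$regional, n = Inf)
  invisible(x)
}
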