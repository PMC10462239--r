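#' Simulate gridded daily or seasonal fields from a truth configuration
#'
#' The generative model inverts the analysis model. Writing `y(c)` for the
#' June-to-May "pollution year" containing day `d` (the year of the most
#' recent 1 June) and `dT(c, y)` for that year's summer-mean temperature
#' anomaly at cell `c`:
#' \deqn{pollutant(c, d) = baseline(c) + trend(c) (y - y_0) +
#'       \beta(c, y) dT(c, y) + \epsilon(c, d)}
#' with `eps` iid Gaussian daily noise. Daily mean temperature is a
#' sinusoidal seasonal cycle plus `dT(c, y(c))`, and `tmax`/`tmin` are
#' constructed symmetrically around it so that `(tmax + tmin)/2` reproduces
#' it exactly. Indexing the response by the pollution year makes both the
#' JJA mean and the June-to-May annual mean respond with exactly `beta` per
#' degree, so estimator self-consistency can be checked to machine
#' precision at zero noise.
#'
#' Species fields partition the deterministic part of PM2.5 by
#' `species_shares`, carry their own `beta_<species>` sensitivities, and
#' split the daily noise by share; the `other` column is the remainder, so
#' the species columns plus `other` always sum to `pm25` exactly.
#'
#' @param truth A [make_truth()] configuration.
#' @param frequency `"daily"` for full daily series, `"seasonal"` to
#'   generate JJA and June-to-May annual means directly (same model, noise
#'   sd scaled by `1/sqrt(days in window)`; much faster for simulation
#'   studies).
#' @param include_species Also simulate per-species daily PM2.5 fields
#'   (daily frequency only).
#' @param seed Seed for the stochastic draws; defaults to `truth$seed`.
#' @return For `"daily"`: a list of class `sim_fields` with tibbles
#'   `$temperature` (`cell_id`, `date`, `tmax`, `tmin`), `$pollutant`
#'   (`cell_id`, `date`, `pm25`, `o3`), optionally `$species`, plus
#'   `$anomalies` (the true `dtemp` draws per cell-year) and `$truth`.
#'   For `"seasonal"`: a tibble with one row per cell-year (`cell_id`,
#'   `lat`, `lon`, `year`, `dtemp_true`, `temp`, `pm_jja`, `pm_ann`,
#'   `o3_jja`).
#' @examples
#' truth <- make_truth(1, n_lat = 4, n_lon = 4, years = 2000:2004,
#'                     scenario = "flat")
#' seas <- simulate_fields(truth, frequency = "seasonal")
#' head(seas)
#' @export
simulate_fields <- function(truth,
                            frequency = c("daily", "seasonal"),
                            include_species = FALSE,
                            seed = truth$seed) {
  stopifnot(inherits(truth, "truth_config"))
  frequency <- match.arg(frequency)
  anoms <- draw_temp_anomalies(truth, seed = seed)
  if (frequency == "seasonal") {
    return(simulate_seasonal_impl(truth, anoms, seed))
  }
  simulate_daily_impl(truth, anoms, seed, include_species)
}

simulate_seasonal_impl <- function(truth, anoms, seed) {
  g <- truth$grid
  y0 <- min(truth$years)
  base <- tidyr::expand_grid(cell_id = g$cell_id, year = truth$years)
  base <- dplyr::left_join(base, anoms, by = c("cell_id", "year"))
  base <- dplyr::left_join(
    base,
    dplyr::select(g, "cell_id", "lat", "lon", "beta_pm", "beta_pm_late",
                  "beta_o3", "beta_o3_late", "trend_pm", "trend_o3",
                  "baseline_pm", "baseline_o3"),
    by = "cell_id"
  )
  sd_pm <- truth$noise_sd_daily[["pm"]]
  sd_o3 <- truth$noise_sd_daily[["o3"]]
  out <- withr::with_seed(seed + 1L, {
    n <- nrow(base)
    dplyr::transmute(
      base,
      cell_id = .data$cell_id, lat = .data$lat, lon = .data$lon,
      year = .data$year,
      dtemp_true = .data$dtemp,
      temp = jja_base_temp() + .data$dtemp,
      pm_jja = .data$baseline_pm + .data$trend_pm * (.data$year - y0) +
        beta_for_year(.data$beta_pm, .data$beta_pm_late, .data$year,
                      truth$shift_year) * .data$dtemp +
        stats::rnorm(n, sd = sd_pm / sqrt(92)),
      pm_ann = .data$baseline_pm + .data$trend_pm * (.data$year - y0) +
        beta_for_year(.data$beta_pm, .data$beta_pm_late, .data$year,
                      truth$shift_year) * .data$dtemp +
        stats::rnorm(n, sd = sd_pm / sqrt(365)),
      o3_jja = .data$baseline_o3 + .data$trend_o3 * (.data$year - y0) +
        beta_for_year(.data$beta_o3, .data$beta_o3_late, .data$year,
                      truth$shift_year) * .data$dtemp +
        stats::rnorm(n, sd = sd_o3 / sqrt(92))
    )
  })
  tibble::as_tibble(out)
}

simulate_daily_impl <- function(truth, anoms, seed, include_species) {
  g <- truth$grid
  y0 <- min(truth$years)
  dates <- seq(as.Date(sprintf("%d-01-01", min(truth$years))),
               as.Date(sprintf("%d-12-31", max(truth$years))), by = "day")
  cal <- tibble::tibble(
    date = dates,
    doy = doy_noleap(dates),
    pollution_year = pollution_year(dates)
  )
  base <- tidyr::expand_grid(cell_id = g$cell_id, date = dates)
  base <- dplyr::left_join(base, cal, by = "date")
  base <- dplyr::left_join(base, anoms,
                           by = c("cell_id", "pollution_year" = "year"))
  base <- dplyr::left_join(
    base,
    dplyr::select(g, "cell_id", dplyr::starts_with("beta_"),
                  "trend_pm", "trend_o3", "baseline_pm", "baseline_o3"),
    by = "cell_id"
  )

  tmean <- seasonal_cycle(base$doy) + base$dtemp
  temperature <- tibble::tibble(
    cell_id = base$cell_id, date = base$date,
    tmax = tmean + 5, tmin = tmean - 5
  )

  yr_idx <- base$pollution_year - y0
  bpm <- beta_for_year(base$beta_pm, base$beta_pm_late,
                       base$pollution_year, truth$shift_year)
  bo3 <- beta_for_year(base$beta_o3, base$beta_o3_late,
                       base$pollution_year, truth$shift_year)
  det_pm <- base$baseline_pm + base$trend_pm * yr_idx
  n <- nrow(base)
  noise <- withr::with_seed(seed + 1L, {
    list(pm = stats::rnorm(n, sd = truth$noise_sd_daily[["pm"]]),
         o3 = stats::rnorm(n, sd = truth$noise_sd_daily[["o3"]]))
  })
  pm25 <- det_pm + bpm * base$dtemp + noise$pm
  o3 <- base$baseline_o3 + base$trend_o3 * yr_idx + bo3 * base$dtemp + noise$o3
  pollutant <- tibble::tibble(cell_id = base$cell_id, date = base$date,
                              pm25 = pm25, o3 = o3)

  out <- list(temperature = temperature, pollutant = pollutant,
              anomalies = anoms, truth = truth)
  if (include_species) {
    sp <- tibble::tibble(cell_id = base$cell_id, date = base$date)
    acc <- 0
    for (s in names(truth$species_shares)) {
      share <- truth$species_shares[[s]]
      bsp <- base[[paste0("beta_", s)]]
      sp[[s]] <- share * det_pm + bsp * base$dtemp + share * noise$pm
      acc <- acc + sp[[s]]
    }
    sp$other <- pm25 - acc
    out$species <- sp
  }
  structure(out, class = "sim_fields")
}

# June-to-May pollution year: the calendar year of the most recent 1 June.
pollution_year <- function(dates) {
  y <- as.integer(format(dates, "%Y"))
  m <- as.integer(format(dates, "%m"))
  ifelse(m >= 6, y, y - 1L)
}

# Leap-invariant day of year: a calendar date maps to the same cycle value
# every year (29 Feb shares day 59), so seasonal means of the cycle are
# identical across years and cancel exactly under detrending.
doy_noleap <- function(dates) {
  doy <- as.integer(format(dates, "%j"))
  leap <- lubridate::leap_year(dates) & doy > 59
  doy - as.integer(leap)
}

# Sinusoidal mean-temperature seasonal cycle peaking in mid-July.
seasonal_cycle <- function(doy) {
  15 + 12 * sin(2 * pi * (doy - 105) / 365.25)
}

jja_base_temp <- function() {
  dates <- seq(as.Date("2001-06-01"), as.Date("2001-08-31"), by = "day")
  mean(seasonal_cycle(as.integer(format(dates, "%j"))))
}

beta_for_year <- function(beta_early, beta_late, year, shift_year) {
  ifelse(year >= shift_year, beta_late, beta_early)
}

#' Sample a sparse station network from a gridded daily field
#'
#' Places `n_sites` monitors at distinct grid-cell centers, samples the
#' cell's series every `sampling_interval_days` days (24-h samples every
#' three days is the typical monitoring schedule), and drops each scheduled
#' record independently with probability `miss_rate`.
#'
#' @param fields Daily gridded tibble with columns `cell_id`, `date` and the
#'   variable column `var`.
#' @param var Name of the variable column to record (string or bare name).
#' @param grid Tibble mapping `cell_id` to `lat`/`lon` (e.g. `truth$grid`).
#' @param n_sites Number of monitors; must not exceed the number of cells.
#' @param sampling_interval_days Days between scheduled samples.
#' @param miss_rate Independent dropout probability in \[0, 1).
#' @param seed Integer seed; placement, schedule phase and dropout are
#'   deterministic in it.
#' @param units Units string recorded in the output.
#' @return Tidy station tibble: `site_id`, `lat`, `lon`, `date`, `variable`,
#'   `units`, `value` (one row per retained record).
#' @export
sample_stations <- function(fields, var, grid, n_sites,
                            sampling_interval_days = 3, miss_rate = 0,
                            seed = 1, units = "ug/m3") {
  var <- rlang::as_name(rlang::ensym(var))
  stopifnot(var %in% names(fields), all(c("cell_id", "lat", "lon") %in% names(grid)))
  if (miss_rate < 0 || miss_rate >= 1) stop("`miss_rate` must be in [0, 1)")
  cells <- unique(fields$cell_id)
  if (n_sites > length(cells)) {
    stop("n_sites (", n_sites, ") exceeds number of grid cells (",
         length(cells), ")")
  }
  withr::with_seed(seed, {
    site_cells <- sample(cells, n_sites)
    d0 <- min(fields$date)
    recs <- fields |>
      dplyr::filter(.data$cell_id %in% site_cells,
                    as.integer(.data$date - d0) %% sampling_interval_days == 0) |>
      dplyr::select("cell_id", "date", value = dplyr::all_of(var))
    if (miss_rate > 0) {
      keep <- stats::runif(nrow(recs)) >= miss_rate
      recs <- recs[keep, ]
    }
    recs |>
      dplyr::left_join(dplyr::select(grid, "cell_id", "lat", "lon"),
                       by = "cell_id") |>
      dplyr::transmute(
        site_id = sprintf("S%04d", .data$cell_id),
        lat = .data$lat, lon = .data$lon, date = .data$date,
        variable = var, units = units, value = .data$value
      ) |>
      dplyr::arrange(.data$site_id, .data$date)
  })
}

#' Simulate a clustered population grid
#'
#' Population density is a small rural background plus `n_clusters`
#' Gaussian urban clusters with log-normal peak densities, guaranteeing at
#' least one cell at or above and one below the 400 people/km2 urban cutoff
#' so urban/nonurban stratification is always exercised. Counts are density
#' times cell area; cell areas use `(cell_deg * 111.32 km)^2 * cos(lat)`.
#'
#' @param truth A [make_truth()] configuration (supplies the grid).
#' @param n_clusters Number of urban clusters (>= 1).
#' @param seed Integer seed.
#' @return Tibble: `cell_id`, `lat`, `lon`, `density` (people/km2),
#'   `cell_area` (km2), `count` (people).
#' @export
simulate_population <- function(truth, n_clusters = 3, seed = truth$seed) {
  stopifnot(inherits(truth, "truth_config"))
  if (n_clusters < 1) stop("`n_clusters` must be at least 1")
  g <- truth$grid
  withr::with_seed(seed + 2L, {
    density <- stats::rlnorm(nrow(g), meanlog = log(5), sdlog = 0.5)
    centers <- g[sample(nrow(g), n_clusters), c("lat", "lon")]
    amp <- stats::rlnorm(n_clusters, meanlog = log(2000), sdlog = 0.5)
    sigma <- truth$cell_deg * stats::runif(n_clusters, 1.5, 3)
    for (k in seq_len(n_clusters)) {
      d2 <- (g$lat - centers$lat[k])^2 + (g$lon - centers$lon[k])^2
      density <- density + max(amp[k], 1000) * exp(-d2 / (2 * sigma[k]^2))
    }
    cell_area <- (truth$cell_deg * 111.32)^2 * cos(g$lat * pi / 180)
    tibble::tibble(
      cell_id = g$cell_id, lat = g$lat, lon = g$lon,
      density = density, cell_area = cell_area,
      count = density * cell_area
    )
  })
}

#' Divide the grid into four named analysis regions
#'
#' Splits the domain into West (western longitude third), Central (middle
#' third), and Northeast/Southeast (eastern third split at the median
#' latitude), mirroring a four-region continental partition.
#'
#' @param truth A [make_truth()] configuration.
#' @return Tibble: `cell_id`, `lat`, `lon`, `region` (factor with levels
#'   West, Central, Northeast, Southeast).
#' @export
make_region_mask <- function(truth) {
  stopifnot(inherits(truth, "truth_config"))
  g <- truth$grid
  qlon <- stats::quantile(truth$lon, c(1 / 3, 2 / 3), names = FALSE)
  midlat <- stats::median(truth$lat)
  region <- dplyr::case_when(
    g$lon <= qlon[1] ~ "West",
    g$lon <= qlon[2] ~ "Central",
    g$lat >= midlat ~ "Northeast",
    TRUE ~ "Southeast"
  )
  tibble::tibble(cell_id = g$cell_id, lat = g$lat, lon = g$lon,
                 region = factor(region, levels = c("West", "Central",
                                                    "Northeast", "Southeast")))
}
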