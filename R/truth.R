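#' Build a ground-truth configuration for the synthetic study domain
#'
#' Defines everything the synthetic generator needs: a regular lat/lon grid,
#' per-cell true temperature sensitivities (`beta`), per-cell linear emission
#' trends, baselines, noise levels, the interannual summer-anomaly model, and
#' the species partition of PM2.5. Downstream estimators are checked against
#' these known truths.
#'
#' Scenarios:
#' \describe{
#'   \item{`"smooth"`}{spatially smooth sensitivity fields, PM2.5 beta
#'     rescaled to the `beta_pm` range (default 0--2 ug/m3/C).}
#'   \item{`"flat"`}{constant sensitivity everywhere.}
#'   \item{`"two-region"`}{contrasting betas in the western and eastern grid
#'     halves (defaults 2.0 west, 0.5 east).}
#'   \item{`"decadal-shift"`}{sensitivity changes at `shift_year` (defaults
#'     2.0 before 2010, 0.5 from 2010 on), emulating a decadal change in the
#'     penalty.}
#' }
#'
#' @param seed Integer seed; the whole configuration is deterministic in it.
#' @param n_lat,n_lon Grid dimensions (cells); at least 4 x 4.
#' @param years Inclusive year range covered by the simulation (>= 3 years).
#' @param scenario Named preset, see Details.
#' @param lat0,lon0,cell_deg Grid origin (south-west cell center, degrees)
#'   and cell spacing in degrees.
#' @param beta_pm,beta_o3 Scenario-dependent sensitivity parameters.
#'   For `"flat"` a single value; for `"two-region"` length-2 `c(west, east)`;
#'   for `"decadal-shift"` the early-period value; for `"smooth"` a length-2
#'   range the smooth field is rescaled to.
#' @param beta_pm_late,beta_o3_late Late-period sensitivities for the
#'   `"decadal-shift"` scenario.
#' @param shift_year First year of the late regime for `"decadal-shift"`.
#' @param trend_pm,trend_o3 Per-cell linear trends (units/yr), emulating
#'   anthropogenic emission decline.
#' @param baseline_pm,baseline_o3 Long-term mean levels (ug/m3, ppb).
#' @param noise_sd_daily Named vector `c(pm = , o3 = )` of daily iid noise
#'   standard deviations. The default makes the JJA seasonal-mean noise sd
#'   equal 0.5 units (0.5 * sqrt(92)).
#' @param temp_anom_sd Standard deviation of interannual summer-mean
#'   temperature anomalies (degrees C).
#' @param spatial_corr_len Correlation length (cells) of the Gaussian-kernel
#'   smoothing applied to anomaly and sensitivity fields; 0 disables
#'   smoothing (spatially independent fields).
#' @param species_shares Named fractions of the deterministic PM2.5 mass
#'   assigned to sulfate/nitrate/ammonium/oc/ec; each in \[0,1\], sum <= 1.
#' @param species_beta Optional named list of per-species sensitivities
#'   (scalar per species). Default: `share * beta_pm` per cell.
#'
#' @return An object of class `truth_config`: a list of scalar parameters
#'   plus `$grid`, a tibble with one row per cell (`cell_id`, `lat`, `lon`,
#'   `beta_pm`, `beta_o3`, `beta_pm_late`, `beta_o3_late`, `trend_pm`,
#'   `trend_o3`, `baseline_pm`, `baseline_o3`, and `beta_<species>` columns).
#' @examples
#' truth <- make_truth(seed = 1, n_lat = 6, n_lon = 6, scenario = "flat")
#' truth$grid
#' @export
make_truth <- function(seed,
                       n_lat = 20, n_lon = 30,
                       years = 2000:2016,
                       scenario = c("smooth", "flat", "two-region", "decadal-shift"),
                       lat0 = 30, lon0 = -110, cell_deg = 0.25,
                       beta_pm = NULL, beta_o3 = NULL,
                       beta_pm_late = NULL, beta_o3_late = NULL,
                       shift_year = 2010,
                       trend_pm = -0.25, trend_o3 = -0.4,
                       baseline_pm = 10, baseline_o3 = 45,
                       noise_sd_daily = c(pm = 0.5 * sqrt(92), o3 = sqrt(92)),
                       temp_anom_sd = 0.6,
                       spatial_corr_len = 3,
                       species_shares = c(sulfate = 0.30, nitrate = 0.10,
                                          ammonium = 0.12, oc = 0.25, ec = 0.05),
                       species_beta = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (n_lat < 4 || n_lon < 4) {
    stop("grid must be at least 4 x 4 cells, got ", n_lat, " x ", n_lon)
  }
  years <- sort(unique(as.integer(years)))
  if (length(years) < 3) stop("`years` must span at least 3 years")
  if (cell_deg <= 0) stop("`cell_deg` must be positive")
  if (any(species_shares < 0) || any(species_shares > 1)) {
    stop("each species share must lie in [0, 1]")
  }
  if (sum(species_shares) > 1 + 1e-12) {
    stop("species shares must sum to at most 1, got ", sum(species_shares))
  }
  if (!all(c("pm", "o3") %in% names(noise_sd_daily))) {
    stop("`noise_sd_daily` must be a named vector with elements 'pm' and 'o3'")
  }

  lat <- lat0 + (seq_len(n_lat) - 1) * cell_deg
  lon <- lon0 + (seq_len(n_lon) - 1) * cell_deg
  grid <- tidyr::expand_grid(lat = lat, lon = lon)
  grid <- dplyr::mutate(grid, cell_id = dplyr::row_number(), .before = 1)

  fields <- withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    switch(scenario,
      "flat" = {
        bpm <- beta_pm %||% 1.0
        bo3 <- beta_o3 %||% 3.0
        list(beta_pm = rep(bpm, nrow(grid)), beta_o3 = rep(bo3, nrow(grid)))
      },
      "two-region" = {
        bpm <- beta_pm %||% c(2.0, 0.5)
        bo3 <- beta_o3 %||% c(6.0, 1.5)
        west <- grid$lon < stats::median(lon)
        list(beta_pm = ifelse(west, bpm[1], bpm[2]),
             beta_o3 = ifelse(west, bo3[1], bo3[2]))
      },
      "decadal-shift" = {
        bpm <- beta_pm %||% 2.0
        bo3 <- beta_o3 %||% 5.6
        list(beta_pm = rep(bpm, nrow(grid)), beta_o3 = rep(bo3, nrow(grid)))
      },
      "smooth" = {
        rng_pm <- beta_pm %||% c(0, 2)
        rng_o3 <- beta_o3 %||% c(0, 6)
        f1 <- smooth_field(n_lat, n_lon, spatial_corr_len)
        f2 <- smooth_field(n_lat, n_lon, spatial_corr_len)
        list(beta_pm = rescale_range(as.vector(t(f1)), rng_pm),
             beta_o3 = rescale_range(as.vector(t(f2)), rng_o3))
      }
    )
  })

  grid$beta_pm <- fields$beta_pm
  grid$beta_o3 <- fields$beta_o3
  if (scenario == "decadal-shift") {
    grid$beta_pm_late <- rep(beta_pm_late %||% 0.5, nrow(grid))
    grid$beta_o3_late <- rep(beta_o3_late %||% 1.8, nrow(grid))
  } else {
    grid$beta_pm_late <- grid$beta_pm
    grid$beta_o3_late <- grid$beta_o3
  }
  grid$trend_pm <- rep_len(trend_pm, nrow(grid))
  grid$trend_o3 <- rep_len(trend_o3, nrow(grid))
  grid$baseline_pm <- rep_len(baseline_pm, nrow(grid))
  grid$baseline_o3 <- rep_len(baseline_o3, nrow(grid))
  for (sp in names(species_shares)) {
    b <- if (!is.null(species_beta) && !is.null(species_beta[[sp]])) {
      rep_len(species_beta[[sp]], nrow(grid))
    } else {
      species_shares[[sp]] * grid$beta_pm
    }
    grid[[paste0("beta_", sp)]] <- b
  }

  structure(
    list(seed = as.integer(seed), scenario = scenario,
         n_lat = n_lat, n_lon = n_lon,
         lat = lat, lon = lon, lat0 = lat0, lon0 = lon0, cell_deg = cell_deg,
         years = years, shift_year = shift_year,
         temp_anom_sd = temp_anom_sd, spatial_corr_len = spatial_corr_len,
         noise_sd_daily = noise_sd_daily, species_shares = species_shares,
         grid = grid),
    class = "truth_config"
  )
}

#' @export
print.truth_config <- function(x, ...) {
  cat("<truth_config> scenario:", x$scenario,
      sprintf("| grid %d x %d (%.2f deg)", x$n_lat, x$n_lon, x$cell_deg),
      sprintf("| years %d-%d", min(x$years), max(x$years)),
      sprintf("| seed %d", x$seed), "\n")
  cat("  temp_anom_sd:", x$temp_anom_sd,
      "| corr_len:", x$spatial_corr_len,
      "| noise_sd_daily:", paste(names(x$noise_sd_daily),
                                 signif(x$noise_sd_daily, 3),
                                 sep = "=", collapse = " "), "\n")
  invisible(x)
}

# Smooth a white-noise matrix with a separable Gaussian kernel of width
# `corr_len` cells and renormalise so every cell is marginally N(0, 1).
# corr_len = 0 returns the white noise unchanged.
smooth_field <- function(n_lat, n_lon, corr_len) {
  z <- matrix(stats::rnorm(n_lat * n_lon), n_lat, n_lon)
  if (corr_len <= 0) return(z)
  k_lat <- exp(-outer(seq_len(n_lat), seq_len(n_lat), "-")^2 / (2 * corr_len^2))
  k_lon <- exp(-outer(seq_len(n_lon), seq_len(n_lon), "-")^2 / (2 * corr_len^2))
  sm <- k_lat %*% z %*% t(k_lon)
  norm <- sqrt(rowSums(k_lat^2) %o% rowSums(k_lon^2))
  sm / norm
}

rescale_range <- function(x, range) {
  if (diff(range(x)) == 0) return(rep(mean(range), length(x)))
  range[1] + (x - min(x)) / (max(x) - min(x)) * (range[2] - range[1])
}

# Interannual summer-mean temperature anomaly draws, one spatially
# correlated field per year (plus the year before the first, covering the
# Jan-May tail of the first June-to-May pollution year).
draw_temp_anomalies <- function(truth, seed) {
  yrs <- c(min(truth$years) - 1L, truth$years)
  withr::with_seed(seed, {
    purrr::map_dfr(yrs, function(y) {
      f <- smooth_field(truth$n_lat, truth$n_lon, truth$spatial_corr_len)
      tibble::tibble(
        year = y,
        cell_id = truth$grid$cell_id,
        dtemp = as.vector(t(f)) * truth$temp_anom_sd
      )
    })
  })
}
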