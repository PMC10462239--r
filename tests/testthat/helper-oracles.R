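# Independent brute-force oracles; deliberately naive implementations,
# kept free of the package's own code paths.

# Simple OLS slope via lm().
bf_slope <- function(x, y) unname(stats::coef(stats::lm(y ~ x))[2])

# Detrending residuals via lm() on year.
bf_detrend <- function(year, value) unname(stats::resid(stats::lm(value ~ year)))

# Weighted quantile: smallest value whose cumulative normalised weight
# reaches p, by direct scan.
bf_wquant <- function(values, weights, p) {
  o <- order(values)
  v <- values[o]; w <- weights[o] / sum(weights)
  acc <- 0
  for (i in seq_along(v)) {
    acc <- acc + w[i]
    if (acc >= p - 1e-12) return(v[i])
  }
  v[length(v)]
}

# Enumerate complete months of a daily station tibble by explicit loops.
bf_complete_months <- function(stations, min_days = 7) {
  out <- 0L
  for (s in unique(stations$site_id)) {
    d <- stations[stations$site_id == s & !is.na(stations$value), ]
    ym <- format(d$date, "%Y-%m")
    out <- out + sum(table(ym) >= min_days)
  }
  out
}

# Tiny flat-truth fixture shared across tests.
flat_truth <- function(seed = 1, n = 5, years = 2000:2010, noise = 0) {
  make_truth(seed, n_lat = n, n_lon = n, years = years, scenario = "flat",
             noise_sd_daily = c(pm = noise, o3 = noise))
}

# Seasonal cell-year table joined with its summer temperature, straight
# from the generator (bypasses the daily aggregation for speed).
seasonal_joined <- function(truth, var = "pm_jja") {
  seas <- simulate_fields(truth, frequency = "seasonal")
  dplyr::transmute(seas, cell_id = cell_id, year = year,
                   temp = temp, value = .data[[var]])
}
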