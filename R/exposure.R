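#' Assign population counts to sensitivity-map cells by nearest center
#'
#' Every population cell's count is assigned to the map cell with the
#' nearest center (independently nearest in latitude and longitude, which
#' is the nearest center on a regular grid). Total population is conserved
#' exactly.
#'
#' @param pop Population tibble (`lat`, `lon`, `count`, optionally
#'   `density`).
#' @param map A `sensitivity_map` tibble with `lat`/`lon` columns.
#' @return The map with a `weight` column (assigned population count; 0
#'   for cells receiving no population).
#' @export
align_population <- function(pop, map) {
  stopifnot(all(c("lat", "lon", "count") %in% names(pop)),
            all(c("lat", "lon") %in% names(map)))
  lat_c <- sort(unique(map$lat)); lon_c <- sort(unique(map$lon))
  overlap <- min(pop$lat) <= max(lat_c) + diff(range(lat_c)) &&
    max(pop$lat) >= min(lat_c) - diff(range(lat_c)) &&
    min(pop$lon) <= max(lon_c) + diff(range(lon_c)) &&
    max(pop$lon) >= min(lon_c) - diff(range(lon_c))
  if (!overlap) stop("population and map domains are disjoint")
  assigned <- tibble::tibble(
    lat = lat_c[nearest_index(pop$lat, lat_c)],
    lon = lon_c[nearest_index(pop$lon, lon_c)],
    count = pop$count
  ) |>
    dplyr::group_by(.data$lat, .data$lon) |>
    dplyr::summarise(weight = sum(.data$count), .groups = "drop")
  out <- dplyr::left_join(map, assigned, by = c("lat", "lon")) |>
    dplyr::mutate(weight = dplyr::coalesce(.data$weight, 0))
  new_sensitivity_map(out, window = attr(map, "window"),
                      variable = attr(map, "variable"))
}

# Index of the nearest value of sorted `centers` for each x.
nearest_index <- function(x, centers) {
  if (length(centers) == 1) return(rep(1L, length(x)))
  mids <- head(centers, -1) + diff(centers) / 2
  findInterval(x, mids) + 1L
}

#' Weighted quantiles (left-continuous inverse CDF)
#'
#' The quantile at probability p is the smallest value whose cumulative
#' normalised weight reaches p, with values sorted ascending. With equal
#' weights this reduces to an ordinary type-1 order-statistic quantile.
#'
#' @param values Numeric values (NA dropped with their weights).
#' @param weights Non-negative weights, at least one positive.
#' @param probs Probabilities in (0, 1).
#' @return Tibble: `prob`, `quantile`.
#' @examples
#' weighted_quantiles(c(1, 2, 3), c(1, 1, 8), probs = 0.5)  # 3
#' @export
weighted_quantiles <- function(values, weights,
                               probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  stopifnot(length(values) == length(weights))
  if (any(probs <= 0 | probs >= 1)) stop("`probs` must lie in (0, 1)")
  if (any(weights < 0, na.rm = TRUE)) stop("weights must be non-negative")
  keep <- !is.na(values) & !is.na(weights)
  values <- values[keep]; weights <- weights[keep]
  w_tot <- sum(weights)
  if (w_tot <= 0) stop("all weights are zero")
  o <- order(values)
  v <- values[o]
  cw <- cumsum(weights[o]) / w_tot
  q <- vapply(probs, function(p) v[which(cw >= p - 1e-12)[1]], double(1))
  tibble::tibble(prob = probs, quantile = q)
}

#' High-penalty threshold from the full-record sensitivity map
#'
#' The threshold is the sensitivity experienced by the most-exposed
#' `tail` fraction of the population over the full study period, i.e. the
#' population-weighted quantile at `1 - tail` (default the 75th
#' percentile). Operational rounded values (1 ug/m3/C for summer PM2.5,
#' 0.5 ug/m3/C for annual PM2.5, 3 ppb/C for summer ozone) can be supplied
#' via `override`.
#'
#' @param map Full-record `sensitivity_map`, already passed through
#'   [prepare_exposure_map()] and [align_population()] (or with `weights`
#'   supplied).
#' @param weights Optional weight vector aligned with `map` rows; defaults
#'   to `map$weight`.
#' @param tail Exposed population fraction defining "high" (default 0.25).
#' @param override Optional fixed threshold returned as-is.
#' @return Scalar threshold in sensitivity units.
#' @export
derive_threshold <- function(map, weights = NULL, tail = 0.25,
                             override = NULL) {
  if (!is.null(override)) return(override)
  weights <- weights %||% map$weight
  weighted_quantiles(map$slope, weights, probs = 1 - tail)$quantile
}

#' Weighted fraction of a map at or above a threshold
#'
#' The fraction of total weight carried by cells with sensitivity >= the
#' threshold. `weights = "area"` uses cos-latitude-corrected cell areas;
#' `weights = "population"` uses the `weight` column attached by
#' [align_population()]; a numeric vector is used as-is.
#'
#' @param map A `sensitivity_map` (pass through [prepare_exposure_map()]
#'   first for exposure semantics).
#' @param threshold Sensitivity threshold (units/C).
#' @param weights `"area"`, `"population"`, or a numeric vector.
#' @return Scalar fraction in \[0, 1\].
#' @export
fraction_above <- function(map, threshold, weights = "area") {
  w <- if (is.numeric(weights)) {
    weights
  } else if (identical(weights, "population")) {
    map$weight
  } else if (identical(weights, "area")) {
    cos(map$lat * pi / 180)
  } else {
    stop("`weights` must be 'area', 'population', or a numeric vector")
  }
  keep <- !is.na(map$slope) & !is.na(w)
  sum(w[keep][map$slope[keep] >= threshold]) / sum(w[keep])
}

#' Urban mask from population density
#'
#' Cells with population density at or above `cutoff` people/km2 (default
#' 400) are urban.
#'
#' @param pop Population tibble with a `density` column.
#' @param cutoff Density cutoff in people/km2.
#' @return `pop` with a logical `urban` column added.
#' @export
urban_mask <- function(pop, cutoff = 400) {
  stopifnot("density" %in% names(pop))
  dplyr::mutate(pop, urban = .data$density >= cutoff)
}

#' Urban / nonurban stratified pooled sensitivity
#'
#' Pools anomaly pairs separately over urban and nonurban cells and fits
#' the regional slope in each stratum. An empty (or degenerate) stratum is
#' reported with NA slope and `defined = FALSE`.
#'
#' @param anomalies Anomaly pairs tibble (`unit_id`, `year`, `dtemp`,
#'   `dvalue`).
#' @param mask Tibble with `cell_id` (or `unit_id`) and logical `urban`.
#' @param alpha Significance level.
#' @return Tibble with rows `urban` and `nonurban`: `stratum`, `slope`,
#'   `se`, `p_value`, `n_points`, `defined`.
#' @export
stratified_sensitivity <- function(anomalies, mask, alpha = 0.05) {
  if ("cell_id" %in% names(mask) && !"unit_id" %in% names(mask)) {
    mask <- dplyr::rename(mask, unit_id = "cell_id")
  }
  purrr::map_dfr(c(urban = TRUE, nonurban = FALSE), function(flag) {
    cells <- mask$unit_id[mask$urban == flag]
    pr <- dplyr::filter(anomalies, .data$unit_id %in% cells)
    ok <- nrow(pr) >= 3 && stats::var(pr$dtemp) > 0
    if (!ok) {
      return(tibble::tibble(slope = NA_real_, se = NA_real_,
                            p_value = NA_real_, n_points = nrow(pr),
                            defined = FALSE))
    }
    fit <- regional_sensitivity(pr, alpha = alpha)
    tibble::tibble(slope = fit$slope, se = fit$se, p_value = fit$p_value,
                   n_points = fit$n_points, defined = TRUE)
  }, .id = "stratum")
}

#' Exposure distribution summary of a sensitivity map
#'
#' One-row summary combining the weighted quantiles, the high-penalty
#' threshold and the exceedance fraction, for either population or area
#' weighting.
#'
#' @param map A prepared `sensitivity_map` (clamped, with population
#'   weights attached when `weighting = "population"`).
#' @param weighting `"population"` or `"area"`.
#' @param probs Quantile probabilities.
#' @param threshold High-penalty threshold; when NULL it is derived from
#'   this map at the 75th weighted percentile.
#' @param window,period Labels for the output row.
#' @return One-row tibble: `window`, `period`, `weighting`, `q05`...`q95`
#'   (one column per prob), `threshold`, `fraction_above`, `total_weight`.
#' @export
exposure_distribution <- function(map, weighting = c("population", "area"),
                                  probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                                  threshold = NULL, window = NA,
                                  period = NA) {
  weighting <- match.arg(weighting)
  w <- if (weighting == "population") map$weight else cos(map$lat * pi / 180)
  qs <- weighted_quantiles(map$slope, w, probs = probs)
  threshold <- threshold %||%
    weighted_quantiles(map$slope, w, probs = 0.75)$quantile
  frac <- fraction_above(map, threshold, weights = w)
  wide <- stats::setNames(as.list(qs$quantile),
                          sprintf("q%02d", round(100 * qs$prob)))
  dplyr::bind_cols(
    tibble::tibble(window = window, period = period, weighting = weighting),
    tibble::as_tibble(wide),
    tibble::tibble(threshold = threshold, fraction_above = frac,
                   total_weight = sum(w[!is.na(map$slope)], na.rm = TRUE))
  )
}
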