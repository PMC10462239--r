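#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km; coordinates in decimal
#' degrees. Vectorised and recycled over its arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad / 2
  dlon <- (lon2 - lon1) * rad / 2
  a <- sin(dlat)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon)^2
  2 * 6371 * asin(pmin(sqrt(a), 1))
}

#' Pair pollutant monitors with nearby temperature stations
#'
#' For each pollutant site, all temperature stations within
#' `radius_km` great-circle distance are averaged datewise into a single
#' co-located temperature series, which is then joined to the site's
#' records by date. Pollutant sites with no in-radius temperature station
#' are dropped (with a message).
#'
#' @param pollutant_sites,temp_stations Tidy station tibbles with columns
#'   `site_id`, `lat`, `lon`, `date`, `value`.
#' @param radius_km Co-location radius (default 30 km).
#' @return Tibble: `site_id`, `lat`, `lon`, `date`, `value` (pollutant),
#'   `temp` (mean over in-radius stations), `n_temp_stations`.
#' @export
colocate_station_pairs <- function(pollutant_sites, temp_stations,
                                   radius_km = 30) {
  stopifnot(radius_km > 0)
  psites <- dplyr::distinct(pollutant_sites, .data$site_id, .data$lat, .data$lon)
  tsites <- dplyr::distinct(temp_stations, .data$site_id, .data$lat, .data$lon)
  pairs <- tidyr::expand_grid(
    p = seq_len(nrow(psites)), t = seq_len(nrow(tsites))
  ) |>
    dplyr::mutate(dist = haversine_km(psites$lat[.data$p], psites$lon[.data$p],
                                      tsites$lat[.data$t], tsites$lon[.data$t])) |>
    dplyr::filter(.data$dist <= radius_km)
  matched <- unique(pairs$p)
  dropped <- nrow(psites) - length(matched)
  if (dropped > 0) {
    message(dropped, " pollutant site(s) had no temperature station within ",
            radius_km, " km and were dropped")
  }
  if (length(matched) == 0) {
    return(tibble::tibble(site_id = character(), lat = double(),
                          lon = double(), date = as.Date(character()),
                          value = double(), temp = double(),
                          n_temp_stations = integer()))
  }
  link <- tibble::tibble(site_id = psites$site_id[pairs$p],
                         temp_site = tsites$site_id[pairs$t])
  temp_avg <- temp_stations |>
    dplyr::select(temp_site = "site_id", "date", temp = "value") |>
    dplyr::inner_join(link, by = "temp_site",
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$site_id, .data$date) |>
    dplyr::summarise(temp = mean(.data$temp, na.rm = TRUE),
                     .groups = "drop")
  n_ts <- dplyr::count(link, .data$site_id, name = "n_temp_stations")
  pollutant_sites |>
    dplyr::select("site_id", "lat", "lon", "date", "value") |>
    dplyr::inner_join(temp_avg, by = c("site_id", "date")) |>
    dplyr::left_join(n_ts, by = "site_id")
}

#' Extract grid series co-located with station sites
#'
#' Returns, per site, the series of the grid cell(s) whose centers fall
#' within `radius_km` of the site; multiple in-radius cells are averaged
#' datewise. Sites with no cell center in radius are dropped with a
#' warning.
#'
#' @param grid_daily Gridded daily tibble with `cell_id`, `date` and the
#'   value column.
#' @param sites Station tibble (or site table) with `site_id`, `lat`, `lon`.
#' @param coords Tibble mapping `cell_id` to `lat`/`lon`.
#' @param value Bare name of the value column in `grid_daily`.
#' @param radius_km Co-location radius (default 5 km).
#' @return Tibble: `site_id`, `date`, `value` (mean over in-radius cells),
#'   `n_cells`.
#' @export
extract_colocated_grid <- function(grid_daily, sites, coords, value,
                                   radius_km = 5) {
  stopifnot(radius_km > 0)
  value <- rlang::enquo(value)
  s <- dplyr::distinct(sites, .data$site_id, .data$lat, .data$lon)
  pairs <- tidyr::expand_grid(
    si = seq_len(nrow(s)), ci = seq_len(nrow(coords))
  ) |>
    dplyr::mutate(dist = haversine_km(s$lat[.data$si], s$lon[.data$si],
                                      coords$lat[.data$ci], coords$lon[.data$ci])) |>
    dplyr::filter(.data$dist <= radius_km)
  dropped <- setdiff(seq_len(nrow(s)), unique(pairs$si))
  if (length(dropped) > 0) {
    warning(length(dropped), " site(s) had no grid cell center within ",
            radius_km, " km and were dropped", call. = FALSE)
  }
  if (nrow(pairs) == 0) {
    return(tibble::tibble(site_id = character(), date = as.Date(character()),
                          value = double(), n_cells = integer()))
  }
  link <- tibble::tibble(site_id = s$site_id[pairs$si],
                         cell_id = coords$cell_id[pairs$ci])
  grid_daily |>
    dplyr::select("cell_id", "date", value = !!value) |>
    dplyr::inner_join(link, by = "cell_id", relationship = "many-to-many") |>
    dplyr::group_by(.data$site_id, .data$date) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     n_cells = dplyr::n(), .groups = "drop")
}
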