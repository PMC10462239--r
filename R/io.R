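#' Write / read a tidy station table as CSV
#'
#' CSV with header `site_id,lat,lon,date,variable,units,value` and
#' ISO-8601 dates.
#'
#' @param stations Station tibble.
#' @param path File path.
#' @return `read_stations_csv()` returns the station tibble.
#' @export
write_stations_csv <- function(stations, path) {
  cols <- c("site_id", "lat", "lon", "date", "variable", "units", "value")
  stopifnot(all(cols %in% names(stations)))
  readr::write_csv(stations[, cols], path)
  invisible(path)
}

#' @rdname write_stations_csv
#' @export
read_stations_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(), lat = readr::col_double(),
    lon = readr::col_double(), date = readr::col_date(),
    variable = readr::col_character(), units = readr::col_character(),
    value = readr::col_double()
  ))
}

#' Serialise / restore a truth configuration as plain text
#'
#' Scalar parameters go into a `key = value` header, the per-cell grid
#' into an attached CSV block, so a simulation's ground truth can be kept
#' alongside its outputs for reproducibility.
#'
#' @param truth A `truth_config`.
#' @param path File path (plain text).
#' @return `read_truth_config()` returns the restored `truth_config`.
#' @export
write_truth_config <- function(truth, path) {
  stopifnot(inherits(truth, "truth_config"))
  scalars <- c(
    seed = truth$seed, scenario = truth$scenario,
    n_lat = truth$n_lat, n_lon = truth$n_lon,
    lat0 = truth$lat0, lon0 = truth$lon0, cell_deg = truth$cell_deg,
    years = paste(range(truth$years), collapse = ":"),
    shift_year = truth$shift_year,
    temp_anom_sd = truth$temp_anom_sd,
    spatial_corr_len = truth$spatial_corr_len,
    noise_sd_daily_pm = truth$noise_sd_daily[["pm"]],
    noise_sd_daily_o3 = truth$noise_sd_daily[["o3"]],
    species_shares = paste(names(truth$species_shares),
                           truth$species_shares, sep = "=", collapse = ";")
  )
  header <- paste(names(scalars), unname(scalars), sep = " = ")
  grid_csv <- utils::capture.output(
    utils::write.csv(truth$grid, row.names = FALSE))
  writeLines(c(header, "[grid]", grid_csv), path)
  invisible(path)
}

#' @rdname write_truth_config
#' @export
read_truth_config <- function(path) {
  lines <- readLines(path)
  split_at <- which(lines == "[grid]")
  kv <- strsplit(lines[seq_len(split_at - 1)], " = ", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  shares_kv <- strsplit(strsplit(vals[["species_shares"]], ";")[[1]], "=")
  shares <- stats::setNames(as.numeric(vapply(shares_kv, `[`, "", 2)),
                            vapply(shares_kv, `[`, "", 1))
  yr <- as.integer(strsplit(vals[["years"]], ":")[[1]])
  grid <- readr::read_csv(I(paste(lines[(split_at + 1):length(lines)],
                                  collapse = "\n")),
                          show_col_types = FALSE)
  num <- function(k) as.numeric(vals[[k]])
  structure(
    list(seed = as.integer(vals[["seed"]]), scenario = vals[["scenario"]],
         n_lat = as.integer(vals[["n_lat"]]), n_lon = as.integer(vals[["n_lon"]]),
         lat = sort(unique(grid$lat)), lon = sort(unique(grid$lon)),
         lat0 = num("lat0"), lon0 = num("lon0"), cell_deg = num("cell_deg"),
         years = yr[1]:yr[2], shift_year = as.integer(vals[["shift_year"]]),
         temp_anom_sd = num("temp_anom_sd"),
         spatial_corr_len = num("spatial_corr_len"),
         noise_sd_daily = c(pm = num("noise_sd_daily_pm"),
                            o3 = num("noise_sd_daily_o3")),
         species_shares = shares,
         grid = tibble::as_tibble(grid)),
    class = "truth_config"
  )
}

#' Write / read a gridded series as CF-style NetCDF
#'
#' Optional NetCDF backend (requires the `ncdf4` package): dimensions
#' `time`/`lat`/`lon`, a `units` attribute and `_FillValue` for missing
#' cells. The tidy-CSV writers remain the primary interchange format.
#'
#' @param data Long gridded tibble with `lat`, `lon`, a time column and
#'   one value column.
#' @param path File path.
#' @param var Bare name of the value column.
#' @param time Bare name of the time column (dates or year labels).
#' @param units Units attribute string.
#' @return `read_gridded_nc()` returns a long tibble `lat`, `lon`, `time`,
#'   `value`.
#' @export
write_gridded_nc <- function(data, path, var, time = year, units = "") {
  if (!requireNamespace("ncdf4", quietly = TRUE)) {
    stop("the NetCDF backend requires the 'ncdf4' package")
  }
  var <- rlang::as_name(rlang::ensym(var))
  time_nm <- rlang::as_name(rlang::ensym(time))
  lat <- sort(unique(data$lat)); lon <- sort(unique(data$lon))
  tvals <- sort(unique(data[[time_nm]]))
  t_num <- if (inherits(tvals, "Date")) as.numeric(tvals) else as.numeric(tvals)
  dims <- list(
    ncdf4::ncdim_def("lon", "degrees_east", lon),
    ncdf4::ncdim_def("lat", "degrees_north", lat),
    ncdf4::ncdim_def("time",
                     if (inherits(tvals, "Date")) "days since 1970-01-01"
                     else "year", t_num, unlim = TRUE)
  )
  fill <- -9999
  v <- ncdf4::ncvar_def(var, units, dims, missval = fill, prec = "double")
  arr <- array(NA_real_, c(length(lon), length(lat), length(tvals)))
  i <- match(data$lon, lon); j <- match(data$lat, lat)
  k <- match(data[[time_nm]], tvals)
  arr[cbind(i, j, k)] <- data[[var]]
  nc <- ncdf4::nc_create(path, v)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, v, arr)
  invisible(path)
}

#' @rdname write_gridded_nc
#' @export
read_gridded_nc <- function(path, var = NULL) {
  if (!requireNamespace("ncdf4", quietly = TRUE)) {
    stop("the NetCDF backend requires the 'ncdf4' package")
  }
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  var <- var %||% names(nc$var)[1]
  arr <- ncdf4::ncvar_get(nc, var, collapse_degen = FALSE)
  lon <- as.vector(nc$dim$lon$vals); lat <- as.vector(nc$dim$lat$vals)
  tvals <- as.vector(nc$dim$time$vals)
  if (grepl("days since 1970-01-01", nc$dim$time$units %||% "")) {
    tvals <- as.Date(tvals, origin = "1970-01-01")
  }
  # array dims are (lon, lat, time); as.vector varies lon fastest, matching
  # expand_grid(time, lat, lon) row order
  out <- tidyr::expand_grid(time = tvals, lat = lat, lon = lon)
  out$value <- as.vector(arr)
  out
}
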