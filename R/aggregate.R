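#' Daily mean temperature from daily maxima and minima
#'
#' The daily mean is `(tmax + tmin) / 2`; a day is missing whenever either
#' input is missing.
#'
#' @param data Tibble of daily records with `tmax` and `tmin` columns (names
#'   configurable) and optionally a `date` column, which must be unique
#'   (per `unit` when a unit column is given).
#' @param tmax,tmin,date,unit Bare column names.
#' @return `data` with a `tmean` column added.
#' @examples
#' daily_mean_temperature(tibble::tibble(date = Sys.Date(), tmax = 30, tmin = 20))
#' @export
daily_mean_temperature <- function(data, tmax = tmax, tmin = tmin,
                                   date = date, unit = NULL) {
  tmax <- rlang::enquo(tmax); tmin <- rlang::enquo(tmin)
  date <- rlang::enquo(date); unit <- rlang::enquo(unit)
  if (rlang::as_name(date) %in% names(data)) {
    keys <- if (!rlang::quo_is_null(unit)) {
      paste(dplyr::pull(data, !!unit), dplyr::pull(data, !!date))
    } else {
      as.character(dplyr::pull(data, !!date))
    }
    if (anyDuplicated(keys)) {
      stop("duplicate dates: tmax/tmin records are misaligned")
    }
  }
  dplyr::mutate(data, tmean = (!!tmax + !!tmin) / 2)
}

#' Monthly means under the daily-completeness filter
#'
#' A calendar month is complete if it has at least `min_days` non-missing
#' daily values (the default 7 encodes the "more than 6 daily measurements"
#' rule); the monthly value is the plain mean of the available days and is
#' reported only for complete months.
#'
#' @param data Daily tibble with a date column, a value column and a unit
#'   (site or cell) identifier column.
#' @param value,unit,date Bare column names.
#' @param min_days Minimum non-missing daily values for a complete month.
#' @return Tibble: `unit_id`, `year`, `month`, `value` (NA when
#'   incomplete), `n_contributing`, `complete`.
#' @export
monthly_mean <- function(data, value, unit = cell_id, date = date,
                         min_days = 7) {
  stopifnot(min_days >= 1)
  value <- rlang::enquo(value); unit <- rlang::enquo(unit)
  date <- rlang::enquo(date)
  data |>
    dplyr::group_by(unit_id = !!unit,
                    year = lubridate::year(!!date),
                    month = lubridate::month(!!date)) |>
    dplyr::summarise(
      n_contributing = sum(!is.na(!!value)),
      value = mean(!!value, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      complete = .data$n_contributing >= min_days,
      value = dplyr::if_else(.data$complete, .data$value, NA_real_)
    ) |>
    dplyr::select("unit_id", "year", "month", "value",
                  "n_contributing", "complete")
}

#' Summer-mean values under the monthly-completeness filter
#'
#' The summer mean is the equal-weight mean of the available complete
#' monthly means within the summer window (JJA by default) and is reported
#' when at least `min_months` of them are available.
#'
#' @param monthlies Output of [monthly_mean()].
#' @param min_months Minimum complete months for a complete summer.
#' @param months Integer month set defining summer (default `6:8`, JJA).
#' @return Tibble: `unit_id`, `year`, `window` (`"JJA"` for the default
#'   month set), `value`, `n_contributing` (months), `complete`.
#' @export
summer_mean <- function(monthlies, min_months = 2, months = 6:8) {
  stopifnot(length(months) >= 1)
  label <- if (identical(sort(unique(months)), 6:8)) "JJA" else {
    paste(month.abb[sort(unique(months))], collapse = "")
  }
  monthlies |>
    dplyr::filter(.data$month %in% months, .data$complete) |>
    dplyr::group_by(.data$unit_id, .data$year) |>
    dplyr::summarise(n_contributing = dplyr::n(),
                     value = mean(.data$value), .groups = "drop") |>
    window_complete(min_months, label)
}

#' June-to-May annual means under the monthly-completeness filter
#'
#' The annual window labelled `y` runs June of year `y` through May of year
#' `y + 1` (the 12 months after the labelled summer, capturing lagged
#' effects of a warm summer). It is complete with at least `min_months`
#' available monthly means (default 9, encoding "more than eight").
#'
#' @inheritParams summer_mean
#' @return Tibble: `unit_id`, `year` (label year), `window`
#'   (`"ANN_JunMay"`), `value`, `n_contributing`, `complete`.
#' @export
annual_mean_jun_may <- function(monthlies, min_months = 9) {
  monthlies |>
    dplyr::filter(.data$complete) |>
    dplyr::mutate(year = dplyr::if_else(.data$month >= 6, .data$year,
                                        .data$year - 1)) |>
    dplyr::group_by(.data$unit_id, .data$year) |>
    dplyr::summarise(n_contributing = dplyr::n(),
                     value = mean(.data$value), .groups = "drop") |>
    window_complete(min_months, "ANN_JunMay")
}

window_complete <- function(x, min_months, label) {
  x |>
    dplyr::mutate(
      window = label,
      complete = .data$n_contributing >= min_months,
      value = dplyr::if_else(.data$complete, .data$value, NA_real_)
    ) |>
    dplyr::select("unit_id", "year", "window", "value",
                  "n_contributing", "complete")
}

#' Site eligibility under the long-record rule
#'
#' A site (or cell) enters the sensitivity diagnosis only with at least
#' `min_years` complete seasonal values within the study years (default 11
#' within 2000--2016).
#'
#' @param seasonal Output of [summer_mean()] or [annual_mean_jun_may()].
#' @param min_years Minimum complete years.
#' @param years Optional study-year range to count within.
#' @return Tibble: `unit_id`, `n_years_complete`, `eligible`.
#' @export
site_eligibility <- function(seasonal, min_years = 11, years = NULL) {
  stopifnot(min_years >= 1)
  x <- dplyr::filter(seasonal, .data$complete)
  if (!is.null(years)) x <- dplyr::filter(x, .data$year %in% years)
  x |>
    dplyr::count(.data$unit_id, name = "n_years_complete") |>
    dplyr::mutate(eligible = .data$n_years_complete >= min_years)
}
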