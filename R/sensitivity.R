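#' Detrend an annual series by OLS residuals on year
#'
#' Residuals of an ordinary least-squares fit of value on year remove the
#' long-term mean and the linear trend in one step (the trend stands in for
#' the influence of anthropogenic emission decline). The result is the
#' interannual anomaly series used in all slope fits: mean-zero and
#' orthogonal to the centered year index by construction.
#'
#' @param data Tibble of one series with year and value columns; missing
#'   values are dropped before fitting. At least 3 distinct years with
#'   non-missing values are required.
#' @param year,value Bare column names.
#' @return Tibble: `year`, `anomaly`.
#' @examples
#' detrend(tibble::tibble(year = 2000:2004, value = c(1, 3, 2, 5, 4)))
#' @export
detrend <- function(data, year = year, value = value) {
  year <- rlang::enquo(year); value <- rlang::enquo(value)
  x <- dplyr::pull(data, !!year)
  y <- dplyr::pull(data, !!value)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("detrending needs at least 3 non-missing years")
  if (anyDuplicated(x)) stop("years must be distinct")
  tibble::tibble(year = x, anomaly = ols_resid(x, y))
}

ols_resid <- function(x, y) {
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("zero year variance: cannot detrend")
  y - mean(y) - sum(xc * y) / sxx * xc
}

#' Detrended anomaly pairs per unit
#'
#' For every unit (grid cell or site) with at least `min_years` complete
#' years in the period, detrends the temperature and pollutant seasonal
#' series on year (listwise-deleting years where either is missing) and
#' returns the paired anomalies. Detrending is restricted to `period` when
#' given, so period-specific fits remove the trend of the data they
#' actually use.
#'
#' @param data Tibble with one row per unit-year carrying both seasonal
#'   values.
#' @param temp,value,unit,year Bare column names.
#' @param period Optional year vector restricting (and re-anchoring) the
#'   detrending window.
#' @param min_years Minimum complete years for a unit to be retained.
#' @return Tibble: `unit_id`, `year`, `dtemp`, `dvalue`.
#' @export
anomaly_pairs <- function(data, temp, value, unit = cell_id, year = year,
                          period = NULL, min_years = 3) {
  temp <- rlang::enquo(temp); value <- rlang::enquo(value)
  unit <- rlang::enquo(unit); year <- rlang::enquo(year)
  x <- data |>
    dplyr::transmute(unit_id = !!unit, year = !!year,
                     temp = !!temp, value = !!value) |>
    dplyr::filter(!is.na(.data$temp), !is.na(.data$value))
  if (!is.null(period)) x <- dplyr::filter(x, .data$year %in% period)
  x |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::filter(dplyr::n() >= max(min_years, 3)) |>
    dplyr::mutate(dtemp = ols_resid(.data$year, .data$temp),
                  dvalue = ols_resid(.data$year, .data$value)) |>
    dplyr::ungroup() |>
    dplyr::select("unit_id", "year", "dtemp", "dvalue")
}

#' Temperature sensitivity (climate-penalty slope) of one anomaly series
#'
#' Ordinary least-squares slope of detrended pollutant anomalies on
#' detrended temperature anomalies; standard error and two-sided p-value
#' from the t distribution with n - 2 degrees of freedom. Pairs with either
#' member missing are dropped listwise. A degenerate temperature series
#' (zero variance) yields an NA-slope row rather than an error.
#'
#' @param data Tibble of paired anomalies.
#' @param temp,value Bare column names of the anomaly pair.
#' @param alpha Two-sided significance level for the `significant` flag.
#' @return One-row tibble: `slope`, `intercept`, `se`, `p_value`, `r`,
#'   `n_years`, `significant`.
#' @examples
#' sensitivity_slope(tibble::tibble(dtemp = c(-1, 0, 1), dvalue = c(-2, 0, 2)))
#' @export
sensitivity_slope <- function(data, temp = dtemp, value = dvalue,
                              alpha = 0.05) {
  temp <- rlang::enquo(temp); value <- rlang::enquo(value)
  x <- dplyr::pull(data, !!temp)
  y <- dplyr::pull(data, !!value)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("slope fit needs at least 3 complete pairs")
  fit <- slope_fit(x, y, n_param = 2)
  tibble::tibble(
    slope = fit$slope, intercept = fit$intercept, se = fit$se,
    p_value = fit$p_value, r = fit$r, n_years = n,
    significant = !is.na(fit$p_value) & fit$p_value < alpha
  )
}

# Closed-form simple OLS with t inference; returns NA fields when x is
# degenerate. `n_param` sets the residual degrees of freedom (n - n_param).
slope_fit <- function(x, y, n_param = 2) {
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2); sxy <- sum(xc * yc); syy <- sum(yc^2)
  if (sxx <= 0) {
    return(list(slope = NA_real_, intercept = NA_real_, se = NA_real_,
                p_value = NA_real_, r = NA_real_))
  }
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- max(syy - slope * sxy, 0)
  df <- n - n_param
  se <- if (df > 0) sqrt(rss / df / sxx) else NA_real_
  tstat <- if (!is.na(se) && se > 0) slope / se else NA_real_
  p <- if (!is.na(tstat)) 2 * stats::pt(-abs(tstat), df) else NA_real_
  r <- if (syy > 0) sxy / sqrt(sxx * syy) else NA_real_
  list(slope = slope, intercept = intercept, se = se, p_value = p, r = r)
}

#' Per-cell sensitivity map
#'
#' Applies detrending and the slope fit independently to every grid cell of
#' a joined seasonal tibble. Internally uses the closed-form equivalence
#' with the joint regression of raw values on (temperature, year): the
#' temperature coefficient and the residual sum of squares of that partial
#' regression are identical to detrend-then-fit, which keeps the per-cell
#' computation fully vectorised. Cells with fewer than `min_years` complete
#' years are reported with NA slope.
#'
#' @param data Tibble with one row per cell-year carrying seasonal
#'   temperature and pollutant values.
#' @param value,temp,unit,year Bare column names.
#' @param alpha Significance level for the `significant` flag.
#' @param min_years Minimum complete years per cell.
#' @param coords Optional tibble mapping `unit_id` (or `cell_id`) to
#'   `lat`/`lon`, attached to the output when given.
#' @param window,variable Labels stored as attributes of the returned map.
#' @return A `sensitivity_map` tibble: `unit_id`, (`lat`, `lon`,) `slope`,
#'   `se`, `p_value`, `r`, `n_years`, `significant`.
#' @export
gridwise_sensitivity <- function(data, value, temp, unit = cell_id,
                                 year = year, alpha = 0.05, min_years = 3,
                                 coords = NULL, window = NULL,
                                 variable = NULL) {
  value <- rlang::enquo(value); temp <- rlang::enquo(temp)
  unit <- rlang::enquo(unit); year <- rlang::enquo(year)
  sums <- data |>
    dplyr::transmute(unit_id = !!unit, t = !!year, x = !!temp, y = !!value) |>
    dplyr::filter(!is.na(.data$x), !is.na(.data$y)) |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      stt = sum((.data$t - mean(.data$t))^2),
      sxx = sum((.data$x - mean(.data$x))^2),
      syy = sum((.data$y - mean(.data$y))^2),
      sxt = sum((.data$x - mean(.data$x)) * (.data$t - mean(.data$t))),
      sxy = sum((.data$x - mean(.data$x)) * (.data$y - mean(.data$y))),
      sty = sum((.data$t - mean(.data$t)) * (.data$y - mean(.data$y))),
      .groups = "drop"
    )
  out <- sums |>
    dplyr::mutate(
      sxx_d = .data$sxx - .data$sxt^2 / .data$stt,
      sxy_d = .data$sxy - .data$sxt * .data$sty / .data$stt,
      syy_d = .data$syy - .data$sty^2 / .data$stt,
      ok = .data$n >= max(min_years, 3) & .data$stt > 0 & .data$sxx_d > 1e-12,
      slope = dplyr::if_else(.data$ok, .data$sxy_d / .data$sxx_d, NA_real_),
      rss = pmax(.data$syy_d - .data$slope * .data$sxy_d, 0),
      se = dplyr::if_else(.data$ok & .data$n > 2,
                          sqrt(.data$rss / (.data$n - 2) / .data$sxx_d),
                          NA_real_),
      tstat = .data$slope / .data$se,
      p_value = 2 * stats::pt(-abs(.data$tstat), .data$n - 2),
      r = dplyr::if_else(.data$ok & .data$syy_d > 0,
                         .data$sxy_d / sqrt(.data$sxx_d * .data$syy_d),
                         NA_real_),
      significant = !is.na(.data$p_value) & .data$p_value < alpha
    ) |>
    dplyr::select("unit_id", "slope", "se", "p_value", "r",
                  n_years = "n", "significant")
  if (!is.null(coords)) {
    if ("cell_id" %in% names(coords) && !"unit_id" %in% names(coords)) {
      coords <- dplyr::rename(coords, unit_id = "cell_id")
    }
    out <- dplyr::left_join(dplyr::select(coords, "unit_id", "lat", "lon"),
                            out, by = "unit_id")
  }
  new_sensitivity_map(out, window = window, variable = variable)
}

new_sensitivity_map <- function(x, window = NULL, variable = NULL) {
  x <- tibble::as_tibble(x)
  attr(x, "window") <- window
  attr(x, "variable") <- variable
  class(x) <- unique(c("sensitivity_map", class(x)))
  x
}

#' Clamp negative sensitivities for exposure analysis
#'
#' Negative slopes are treated as no climate penalty (insensitive to
#' temperature) in exposure analysis: they are replaced by 0 while p-values
#' and all other columns are preserved. Idempotent; raw signed maps should
#' be kept for mapping.
#'
#' @param map A `sensitivity_map` (or any tibble with a `slope` column).
#' @return The map with `slope = pmax(slope, 0)`.
#' @export
prepare_exposure_map <- function(map) {
  stopifnot("slope" %in% names(map))
  map$slope <- pmax(map$slope, 0)
  map
}
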