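#' Pool detrended anomaly pairs within a region
#'
#' Concatenates every cell-year (or site-year) anomaly pair whose unit lies
#' in the requested region and whose year lies in the period. The anomalies
#' must already be detrended over the period actually analysed (see
#' [anomaly_pairs()] and its `period` argument).
#'
#' @param anomalies Tibble of anomaly pairs (`unit_id`, `year`, `dtemp`,
#'   `dvalue`).
#' @param mask Region mask tibble (`cell_id` or `unit_id`, `region`).
#' @param region Region code to pool; must be present in the mask.
#' @param period Optional year vector to restrict pooling.
#' @return Tibble of pooled pairs (`unit_id`, `year`, `dtemp`, `dvalue`).
#' @export
pool_region_anomalies <- function(anomalies, mask, region, period = NULL) {
  if ("cell_id" %in% names(mask) && !"unit_id" %in% names(mask)) {
    mask <- dplyr::rename(mask, unit_id = "cell_id")
  }
  cells <- mask$unit_id[mask$region == region]
  if (length(cells) == 0) {
    stop("region '", region, "' is empty or absent from the mask")
  }
  out <- dplyr::filter(anomalies, .data$unit_id %in% cells)
  if (!is.null(period)) out <- dplyr::filter(out, .data$year %in% period)
  out
}

#' Pooled regional sensitivity
#'
#' Ordinary least-squares slope over all pooled anomaly pairs of a region
#' (unweighted across cells/sites), with standard error and two-sided
#' p-value on n - 2 degrees of freedom.
#'
#' @param pairs Pooled pairs tibble (`dtemp`, `dvalue`, `year`).
#' @param alpha Significance level.
#' @param region,window,period Optional labels stored on the fit.
#' @return An object of class `regional_fit` with elements `slope`,
#'   `intercept`, `se`, `p_value`, `r`, `n_points`, `n_years`, and the
#'   pooled `pairs` (used by [bootstrap_regional()] and `autoplot()`).
#'   Use [tidy()] / [glance()] for tabular views.
#' @export
regional_sensitivity <- function(pairs, alpha = 0.05, region = NULL,
                                 window = NULL, period = NULL) {
  pairs <- dplyr::filter(pairs, !is.na(.data$dtemp), !is.na(.data$dvalue))
  if (nrow(pairs) < 3) stop("pooled fit needs at least 3 pairs")
  if (stats::var(pairs$dtemp) == 0) {
    stop("degenerate pooled pairs: zero temperature-anomaly variance")
  }
  fit <- slope_fit(pairs$dtemp, pairs$dvalue, n_param = 2)
  structure(
    list(slope = fit$slope, intercept = fit$intercept, se = fit$se,
         p_value = fit$p_value, r = fit$r,
         n_points = nrow(pairs),
         n_years = dplyr::n_distinct(pairs$year),
         alpha = alpha, region = region, window = window, period = period,
         pairs = pairs, draws = NULL, ci = NULL, B = NULL, seed = NULL),
    class = "regional_fit"
  )
}

#' Year-block bootstrap for a pooled regional sensitivity
#'
#' Resamples years with replacement, keeping all units within a resampled
#' year together (a block bootstrap over years, preserving the strong
#' cross-cell spatial correlation of the anomaly fields), refits the pooled
#' slope for each replicate, and reports the percentile confidence
#' interval and bootstrap standard error. Replicates whose resample has
#' zero temperature-anomaly variance are skipped; more than 10% skipped is
#' an error.
#'
#' Implementation note: a replicate's pooled slope depends on the data only
#' through per-year sums, so replicates are computed from per-year
#' sufficient statistics and a multinomial year-count draw -- numerically
#' identical to refitting from the resampled rows, and O(B x years).
#'
#' @param pairs Pooled pairs tibble or a [regional_sensitivity()] fit.
#' @param B Number of bootstrap replicates (>= 1; default 1000).
#' @param seed Integer seed; draws are deterministic in it.
#' @param conf Confidence level for the percentile interval.
#' @inheritParams regional_sensitivity
#' @return A `regional_fit` with `draws`, `ci` (named `lower`/`upper`),
#'   `se_boot`, `B`, `seed`, and `n_skipped` filled in.
#' @export
bootstrap_regional <- function(pairs, B = 1000, seed = 1, conf = 0.95,
                               alpha = 0.05, region = NULL, window = NULL,
                               period = NULL) {
  if (B < 1) stop("`B` must be at least 1")
  fit <- if (inherits(pairs, "regional_fit")) pairs else {
    regional_sensitivity(pairs, alpha = alpha, region = region,
                         window = window, period = period)
  }
  p <- fit$pairs
  years <- sort(unique(p$year))
  ny <- length(years)
  if (ny < 3) stop("year-block bootstrap needs at least 3 distinct years")

  stats_y <- p |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(n = dplyr::n(),
                     sx = sum(.data$dtemp), sy = sum(.data$dvalue),
                     sxx = sum(.data$dtemp^2), sxy = sum(.data$dtemp * .data$dvalue),
                     .groups = "drop") |>
    dplyr::arrange(.data$year)
  m <- as.matrix(stats_y[, c("n", "sx", "sy", "sxx", "sxy")])

  counts <- withr::with_seed(seed, {
    stats::rmultinom(B, size = ny, prob = rep(1 / ny, ny))
  })
  tot <- t(counts) %*% m  # B x 5
  n <- tot[, 1]; sx <- tot[, 2]; sy <- tot[, 3]
  sxx_c <- tot[, 4] - sx^2 / n
  sxy_c <- tot[, 5] - sx * sy / n
  ok <- sxx_c > 1e-12
  n_skipped <- sum(!ok)
  if (n_skipped > 0.1 * B) {
    stop(n_skipped, " of ", B,
         " bootstrap replicates had zero temperature variance (> 10%)")
  }
  draws <- sxy_c[ok] / sxx_c[ok]
  qq <- stats::quantile(draws, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  fit$draws <- draws
  fit$ci <- c(lower = qq[1], upper = qq[2])
  fit$se_boot <- stats::sd(draws)
  fit$B <- as.integer(B)
  fit$seed <- as.integer(seed)
  fit$n_skipped <- n_skipped
  fit$conf <- conf
  fit
}

#' Decadal change in a pooled regional sensitivity
#'
#' Percent change between an early- and a late-period regional sensitivity,
#' `100 (late - early) / early`, defined only for a positive early slope
#' (a non-positive early slope is a "no penalty to penalty" transition, not
#' a percentage, and is flagged undefined). When both fits carry bootstrap
#' draws, the confidence interval pairs draw i of the early period with
#' draw i of the late period; the change is significant when that interval
#' excludes 0.
#'
#' @param early,late `regional_fit` objects for the same region/window, or
#'   bare numeric slopes.
#' @param conf Confidence level for the paired-draw interval.
#' @return One-row tibble: `region`, `window`, `slope_early`, `slope_late`,
#'   `percent_change`, `ci_lower`, `ci_upper`, `significant`, `undefined`.
#' @examples
#' period_change(5.6, 1.8)  # -67.9% decrease
#' @export
period_change <- function(early, late, conf = 0.95) {
  s_e <- if (inherits(early, "regional_fit")) early$slope else as.numeric(early)
  s_l <- if (inherits(late, "regional_fit")) late$slope else as.numeric(late)
  region <- if (inherits(early, "regional_fit")) early$region else NA
  window <- if (inherits(early, "regional_fit")) early$window else NA
  undefined <- is.na(s_e) || s_e <= 0
  pct <- if (undefined) NA_real_ else 100 * (s_l - s_e) / s_e
  ci <- c(NA_real_, NA_real_); signif <- NA
  d_e <- if (inherits(early, "regional_fit")) early$draws else NULL
  d_l <- if (inherits(late, "regional_fit")) late$draws else NULL
  if (!undefined && !is.null(d_e) && !is.null(d_l)) {
    k <- min(length(d_e), length(d_l))
    de <- d_e[seq_len(k)]; dl <- d_l[seq_len(k)]
    keep <- de > 0
    if (mean(keep) < 0.9) {
      warning(sum(!keep), " of ", k,
              " paired draws had non-positive early slope and were dropped",
              call. = FALSE)
    }
    pct_draws <- 100 * (dl[keep] - de[keep]) / de[keep]
    ci <- stats::quantile(pct_draws, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE)
    signif <- ci[1] > 0 || ci[2] < 0
  }
  out <- tibble::tibble(
    region = as.character(region %||% NA), window = as.character(window %||% NA),
    slope_early = s_e, slope_late = s_l, percent_change = pct,
    ci_lower = ci[1], ci_upper = ci[2],
    significant = signif, undefined = undefined
  )
  class(out) <- unique(c("period_change", class(out)))
  out
}

#' Moving-window regional sensitivity
#'
#' Pooled sensitivity in every `window_years`-long window of consecutive
#' years, detrending within each window. A 17-year record with 5-year
#' windows gives thirteen windows (starts 2000 through 2012 on 2000--2016).
#'
#' @param data Seasonal tibble with one row per unit-year.
#' @param value,temp,unit,year Bare column names.
#' @param window_years Window length in years.
#' @param min_years Minimum complete years per unit within a window.
#' @return Tibble with one row per window: `start_year`, `end_year`,
#'   `slope`, `se`, `p_value`, `n_points`, `n_years`.
#' @export
moving_window_sensitivity <- function(data, value, temp, unit = cell_id,
                                      year = year, window_years = 5,
                                      min_years = 3) {
  value <- rlang::enquo(value); temp <- rlang::enquo(temp)
  unit <- rlang::enquo(unit); year <- rlang::enquo(year)
  yrs <- sort(unique(dplyr::pull(data, !!year)))
  span <- max(yrs) - min(yrs) + 1
  if (window_years > span) stop("window longer than the record span")
  starts <- seq(min(yrs), max(yrs) - window_years + 1)
  purrr::map_dfr(starts, function(s) {
    period <- s:(s + window_years - 1)
    pr <- anomaly_pairs(data, temp = !!temp, value = !!value,
                        unit = !!unit, year = !!year,
                        period = period, min_years = min_years)
    fit <- regional_sensitivity(pr)
    tibble::tibble(start_year = s, end_year = s + window_years - 1,
                   slope = fit$slope, se = fit$se, p_value = fit$p_value,
                   n_points = fit$n_points, n_years = fit$n_years)
  })
}

#' @export
print.regional_fit <- function(x, ...) {
  cat("<regional_fit>",
      if (!is.null(x$region)) paste0("region: ", x$region) else "",
      if (!is.null(x$window)) paste0("window: ", x$window) else "", "\n")
  cat(sprintf("  slope %.4g (OLS se %.3g, p %.3g) on %d pairs / %d years\n",
              x$slope, x$se, x$p_value, x$n_points, x$n_years))
  if (!is.null(x$draws)) {
    cat(sprintf("  bootstrap: B=%d, se %.3g, %d%% CI [%.4g, %.4g]\n",
                x$B, x$se_boot, round(100 * x$conf), x$ci[1], x$ci[2]))
  }
  invisible(x)
}
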