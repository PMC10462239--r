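#' Convert organic carbon to organic aerosol mass
#'
#' Organic aerosol mass is estimated as a fixed multiple of measured
#' organic carbon mass (default factor 2.1). Missing values are preserved.
#'
#' @param oc Organic carbon concentrations (ug/m3).
#' @param factor Positive OC-to-OA conversion factor.
#' @return Organic aerosol concentrations (ug/m3).
#' @examples
#' oc_to_oa(1.0)  # 2.1
#' @export
oc_to_oa <- function(oc, factor = 2.1) {
  if (factor <= 0) stop("`factor` must be positive")
  oc * factor
}

#' Per-species pooled temperature sensitivity
#'
#' Estimates, for each PM2.5 component (sulfate, nitrate, ammonium, OA,
#' EC), the pooled regional slope of detrended seasonal species anomalies
#' on detrended summer-temperature anomalies, reusing the same detrending,
#' completeness semantics and pooling as the total-PM2.5 path. Species with
#' no unit providing at least `min_years` complete years are absent from
#' the output with a warning.
#'
#' @param data Seasonal tibble with one row per unit-year-species:
#'   columns for the unit id, year, species label, species value, and the
#'   co-located seasonal temperature.
#' @param value,temp,unit,year,species Bare column names.
#' @param mask Optional region mask (`cell_id`/`unit_id`, `region`); when
#'   given, slopes are reported per species x region.
#' @param period Optional year vector; detrending is restricted to it.
#' @param alpha Significance level.
#' @param min_years Minimum complete years per unit.
#' @return Tibble: `species`, (`region`,) `slope`, `se`, `p_value`,
#'   `n_points`, `n_units`.
#' @export
component_sensitivity <- function(data, value, temp, unit = site_id,
                                  year = year, species = species,
                                  mask = NULL, period = NULL, alpha = 0.05,
                                  min_years = 3) {
  value <- rlang::enquo(value); temp <- rlang::enquo(temp)
  unit <- rlang::enquo(unit); year <- rlang::enquo(year)
  species <- rlang::enquo(species)
  x <- dplyr::transmute(data, species = !!species, unit_id = !!unit,
                        year = !!year, temp = !!temp, value = !!value)
  sp_all <- unique(x$species)
  regions <- if (is.null(mask)) NA_character_ else {
    as.character(unique(mask$region))
  }
  out <- purrr::map_dfr(sp_all, function(sp) {
    xsp <- dplyr::filter(x, .data$species == sp)
    pr <- tryCatch(
      anomaly_pairs(xsp, temp = temp, value = value, unit = unit_id,
                    year = year, period = period, min_years = min_years),
      error = function(e) NULL
    )
    if (is.null(pr) || nrow(pr) == 0) {
      warning("species '", sp, "' has no eligible units and was skipped",
              call. = FALSE)
      return(NULL)
    }
    purrr::map_dfr(regions, function(rg) {
      prr <- if (is.na(rg)) pr else {
        tryCatch(pool_region_anomalies(pr, mask, rg),
                 error = function(e) pr[0, ])
      }
      if (nrow(prr) < 3 || stats::var(prr$dtemp) == 0) {
        return(tibble::tibble(species = sp, region = rg, slope = NA_real_,
                              se = NA_real_, p_value = NA_real_,
                              n_points = nrow(prr), n_units = 0L))
      }
      fit <- regional_sensitivity(prr, alpha = alpha)
      tibble::tibble(species = sp, region = rg, slope = fit$slope,
                     se = fit$se, p_value = fit$p_value,
                     n_points = fit$n_points,
                     n_units = dplyr::n_distinct(prr$unit_id))
    })
  })
  if (is.null(mask) && nrow(out) > 0) out$region <- NULL
  out
}

#' Species contributions to the overall PM2.5 penalty
#'
#' Normalises non-negative species slopes to contribution fractions:
#' `fraction_s = max(slope_s, 0) / sum_s' max(slope_s', 0)`. Species with a
#' negative slope contribute 0 and are flagged excluded (as a negative
#' nitrate sensitivity is excluded from a contribution pie). All slopes
#' non-positive is an error.
#'
#' @param data Tibble with species labels and slopes.
#' @param slope,species Bare column names.
#' @return `data` with `fraction` and `excluded` columns added; fractions
#'   sum to 1 over included species.
#' @export
contribution_fractions <- function(data, slope = slope, species = species) {
  slope <- rlang::enquo(slope)
  s <- dplyr::pull(data, !!slope)
  if (all(is.na(s)) || all(s[!is.na(s)] <= 0)) {
    stop("no species has a positive slope: contributions undefined")
  }
  pos <- pmax(ifelse(is.na(s), 0, s), 0)
  dplyr::mutate(data, fraction = pos / sum(pos),
                excluded = !is.na(s) & s < 0)
}
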