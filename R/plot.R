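#' Map a sensitivity field
#'
#' Raster map of the per-cell climate-penalty slope with a diverging fill
#' centered at zero; cells failing the minimum-years filter are blank.
#'
#' @param map A `sensitivity_map` with `lat`/`lon` columns.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sensitivity_map <- function(map, ...) {
  stopifnot(all(c("lat", "lon", "slope") %in% names(map)))
  lab <- attr(map, "variable") %||% "sensitivity"
  ggplot2::ggplot(map, ggplot2::aes(x = .data$lon, y = .data$lat,
                                    fill = .data$slope)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = "slope\n(units/°C)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste("Temperature sensitivity:", lab),
                  x = "Longitude", y = "Latitude") +
    ggplot2::theme_minimal()
}

#' Scatter of pooled anomalies with the fitted regional slope
#'
#' @param fit A `regional_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.regional_fit <- function(fit, ...) {
  lab <- sprintf("slope = %.2f %s", fit$slope,
                 if (!is.null(fit$ci)) {
                   sprintf("[%.2f, %.2f]", fit$ci[1], fit$ci[2])
                 } else {
                   sprintf("(se %.2f)", fit$se)
                 })
  ggplot2::ggplot(fit$pairs, ggplot2::aes(x = .data$dtemp, y = .data$dvalue)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         color = "#b2182b") +
    ggplot2::labs(title = paste("Pooled regional sensitivity",
                                fit$region %||% ""),
                  subtitle = lab,
                  x = "ΔT (°C)", y = "Δ pollutant") +
    ggplot2::theme_minimal()
}

#' Box-style plot of population/area-weighted exposure quantiles
#'
#' @param exposure Rows from [exposure_distribution()].
#' @return A ggplot object.
#' @export
plot_exposure_distribution <- function(exposure) {
  qcols <- grep("^q\\d+$", names(exposure), value = TRUE)
  long <- tidyr::pivot_longer(exposure, dplyr::all_of(qcols),
                              names_to = "prob", values_to = "quantile")
  long$prob <- as.numeric(sub("q", "", long$prob)) / 100
  ggplot2::ggplot(long, ggplot2::aes(x = .data$window, y = .data$quantile,
                                     group = interaction(.data$window,
                                                         .data$weighting,
                                                         .data$period),
                                     color = .data$weighting)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = factor(.data$prob))) +
    ggplot2::labs(x = NULL, y = "sensitivity (units/°C)",
                  shape = "exposure\nquantile") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
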