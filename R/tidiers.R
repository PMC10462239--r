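#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pooled regional sensitivity fit
#'
#' @param x A `regional_fit` object.
#' @param ... Unused.
#' @return One-row tibble: `region`, `window`, `period`, `slope`, `se`,
#'   `p_value`, `n_points`, `n_years`, and (when bootstrapped) `se_boot`,
#'   `ci_lower`, `ci_upper`, `B`.
#' @export
tidy.regional_fit <- function(x, ...) {
  out <- tibble::tibble(
    region = x$region %||% NA_character_,
    window = x$window %||% NA_character_,
    period = if (is.null(x$period)) NA_character_ else {
      paste(range(x$period), collapse = "-")
    },
    slope = x$slope, se = x$se, p_value = x$p_value,
    n_points = x$n_points, n_years = x$n_years
  )
  if (!is.null(x$draws)) {
    out$se_boot <- x$se_boot
    out$ci_lower <- x$ci[1]
    out$ci_upper <- x$ci[2]
    out$B <- x$B
  }
  out
}

#' Model-level summary of a pooled regional sensitivity fit
#'
#' @param x A `regional_fit` object.
#' @param ... Unused.
#' @return One-row tibble: `r`, `r.squared`, `n_points`, `n_years`,
#'   `n_skipped` (bootstrap replicates skipped; 0 when not bootstrapped).
#' @export
glance.regional_fit <- function(x, ...) {
  tibble::tibble(r = x$r, r.squared = x$r^2,
                 n_points = x$n_points, n_years = x$n_years,
                 n_skipped = x$n_skipped %||% 0L)
}
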