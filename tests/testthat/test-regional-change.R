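test_that("regional pooling counts and filters match brute force", {
  anoms <- tidyr::expand_grid(unit_id = 1:4, year = 2000:2016) |>
    dplyr::mutate(dtemp = rnorm(dplyr::n()), dvalue = rnorm(dplyr::n()))
  mask <- tibble::tibble(cell_id = 1:4,
                         region = c("A", "A", "B", "B"))
  pooled <- pool_region_anomalies(dplyr::filter(anoms, year <= 2002),
                                  mask, "A")
  expect_equal(nrow(pooled), 6)  # 2 cells x 3 years

  dec <- pool_region_anomalies(anoms, mask, "A", period = 2000:2009)
  expect_true(all(dec$year <= 2009))
  expect_equal(nrow(dec), sum(anoms$unit_id %in% 1:2 & anoms$year <= 2009))
  expect_error(pool_region_anomalies(anoms, mask, "Z"), "empty")

  # pooling is order-invariant
  shuffled <- anoms[sample(nrow(anoms)), ]
  f1 <- regional_sensitivity(pool_region_anomalies(anoms, mask, "B"))
  f2 <- regional_sensitivity(pool_region_anomalies(shuffled, mask, "B"))
  expect_equal(f1$slope, f2$slope)
})

test_that("pooled slope: replication invariance and equal-leverage averaging", {
  yrs <- 2000:2009
  set.seed(41)
  dt <- rnorm(10)
  one <- tibble::tibble(unit_id = 1, year = yrs, dtemp = dt - mean(dt),
                        dvalue = 1.7 * (dt - mean(dt)))
  many <- dplyr::bind_rows(lapply(1:5, function(i) {
    dplyr::mutate(one, unit_id = i)
  }))
  expect_equal(regional_sensitivity(many)$slope,
               regional_sensitivity(one)$slope)

  # two cells, betas 1 and 3, identical temperature draws: pooled slope 2
  two <- dplyr::bind_rows(
    dplyr::mutate(one, dvalue = 1.0 * dtemp, unit_id = 1),
    dplyr::mutate(one, dvalue = 3.0 * dtemp, unit_id = 2)
  )
  expect_equal(regional_sensitivity(two)$slope, 2.0, tolerance = 1e-12)
  expect_equal(regional_sensitivity(two)$slope,
               bf_slope(two$dtemp, two$dvalue), tolerance = 1e-12)

  tri <- tibble::tibble(unit_id = 1, year = 2000:2002,
                        dtemp = c(-1, 0, 1), dvalue = c(-2, 0, 2))
  expect_equal(regional_sensitivity(tri)$slope, 2.0)
  expect_error(regional_sensitivity(tri[1:2, ]), "at least 3")
})

test_that("year-block bootstrap: degenerate data give zero-width CI; contracts hold", {
  yrs <- 2000:2009
  set.seed(42)
  dt <- rnorm(10)
  pairs <- tidyr::expand_grid(unit_id = 1:6, year = yrs) |>
    dplyr::mutate(dtemp = dt[year - 1999] - mean(dt),
                  dvalue = 2.5 * dtemp)
  fit <- bootstrap_regional(pairs, B = 200, seed = 7)
  expect_equal(length(fit$draws), 200)
  expect_equal(unname(fit$ci), c(2.5, 2.5), tolerance = 1e-12)
  expect_true(all(abs(fit$draws - 2.5) < 1e-12))

  expect_error(bootstrap_regional(pairs, B = 0), "at least 1")

  # determinism and CI ordering around the bootstrap median
  noisy <- dplyr::mutate(pairs, dvalue = dvalue + rnorm(dplyr::n(), sd = 0.5))
  b1 <- bootstrap_regional(noisy, B = 300, seed = 5)
  b2 <- bootstrap_regional(noisy, B = 300, seed = 5)
  expect_identical(b1$draws, b2$draws)
  med <- median(b1$draws)
  expect_lte(b1$ci[["lower"]], med)
  expect_gte(b1$ci[["upper"]], med)
})

test_that("bootstrap SE tracks the OLS SE on homoscedastic data", {
  set.seed(43)
  yrs <- 2000:2016
  pairs <- tidyr::expand_grid(unit_id = 1:20, year = yrs) |>
    dplyr::mutate(dtemp = rnorm(dplyr::n(), sd = 0.6),
                  dvalue = 1.5 * dtemp + rnorm(dplyr::n(), sd = 0.5)) |>
    (\(d) anomaly_pairs(d, temp = dtemp, value = dvalue,
                        unit = unit_id))()
  fit <- bootstrap_regional(pairs, B = 1000, seed = 3)
  expect_lt(fit$se_boot / fit$se, 1.5)
  expect_gt(fit$se_boot / fit$se, 1 / 1.5)
})

test_that("period change reproduces the worked percentages and sign guard", {
  pc <- period_change(5.6, 1.8)
  expect_equal(pc$percent_change, 100 * (1.8 - 5.6) / 5.6)
  expect_equal(pc$percent_change, -67.857, tolerance = 1e-3)
  expect_lt(pc$percent_change, -60)

  expect_equal(period_change(3, 3)$percent_change, 0)

  neg <- period_change(-0.1, 1)
  expect_true(neg$undefined)
  expect_true(is.na(neg$percent_change))
})

test_that("period change CI pairs bootstrap draws and flags significance", {
  set.seed(44)
  mk <- function(beta, seed) {
    dt <- rnorm(10, sd = 0.6)
    pairs <- tidyr::expand_grid(unit_id = 1:10, year = 2000:2009) |>
      dplyr::mutate(dtemp = dt[year - 1999],
                    dvalue = beta * dtemp + rnorm(dplyr::n(), sd = 0.3))
    bootstrap_regional(anomaly_pairs(pairs, temp = dtemp, value = dvalue,
                                     unit = unit_id),
                       B = 500, seed = seed)
  }
  pc <- period_change(mk(2.0, 1), mk(0.5, 2))
  expect_false(pc$undefined)
  expect_lt(pc$percent_change, -50)
  expect_true(pc$significant)
  expect_lt(pc$ci_upper, 0)
})

test_that("moving windows: count, full-span equivalence, stationarity", {
  tr <- flat_truth(seed = 8, n = 4, years = 2000:2016, noise = 0.5 * sqrt(92))
  seas <- seasonal_joined(tr)
  mw <- moving_window_sensitivity(seas, value = value, temp = temp,
                                  unit = cell_id, window_years = 5)
  expect_equal(nrow(mw), 13)
  expect_equal(mw$start_year, 2000:2012)

  full <- moving_window_sensitivity(seas, value = value, temp = temp,
                                    unit = cell_id, window_years = 17)
  expect_equal(nrow(full), 1)
  pr <- anomaly_pairs(seas, temp = temp, value = value, unit = cell_id)
  expect_equal(full$slope, regional_sensitivity(pr)$slope, tolerance = 1e-12)

  expect_error(moving_window_sensitivity(seas, value = value, temp = temp,
                                         unit = cell_id, window_years = 30),
               "span")

  # stationary truth: no monotone trend across window slopes (median
  # Mann-Kendall p over seeds stays insignificant)
  pvals <- vapply(1:7, function(s) {
    trs <- flat_truth(seed = s + 100, n = 4, years = 2000:2016,
                      noise = 0.5 * sqrt(92))
    m <- moving_window_sensitivity(seasonal_joined(trs), value = value,
                                   temp = temp, unit = cell_id,
                                   window_years = 5)
    suppressWarnings(cor.test(m$start_year, m$slope,
                              method = "kendall")$p.value)
  }, double(1))
  expect_gt(median(pvals), 0.05)
})
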