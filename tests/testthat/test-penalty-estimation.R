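test_that("detrending removes mean and trend and matches the OLS oracle", {
  const <- detrend(tibble::tibble(year = 2000:2002, value = c(5, 5, 5)))
  expect_equal(const$anomaly, c(0, 0, 0))

  pure <- detrend(tibble::tibble(year = 2000:2009,
                                 value = 3 + 2 * (2000:2009 - 2000)))
  expect_equal(pure$anomaly, rep(0, 10), tolerance = 1e-12)

  d <- detrend(tibble::tibble(year = 2000:2004, value = c(1, 3, 2, 5, 4)))
  expect_equal(d$anomaly, c(-0.4, 0.8, -1.0, 1.2, -0.6))

  expect_error(detrend(tibble::tibble(year = 2000:2001, value = 1:2)),
               "at least 3")
  expect_error(detrend(tibble::tibble(year = c(2000, 2000, 2001),
                                      value = 1:3)), "distinct")
})

test_that("anomalies are mean-zero and trend-orthogonal on random series", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(5:20, 1)
    yrs <- sort(sample(1990:2020, n))
    vals <- rnorm(n, sd = 10) + 0.5 * yrs
    d <- detrend(tibble::tibble(year = yrs, value = vals))
    scale <- max(abs(vals))
    expect_lt(abs(mean(d$anomaly)), 1e-9 * scale)
    expect_lt(abs(sum(d$anomaly * (yrs - mean(yrs)))), 1e-9 * scale * n)
    expect_equal(d$anomaly, bf_detrend(yrs, vals), tolerance = 1e-10)
  }
})

test_that("sensitivity slope matches hand OLS and flags degenerate input", {
  null <- sensitivity_slope(tibble::tibble(dtemp = c(-1, 0, 1),
                                           dvalue = c(0, 0, 0)))
  expect_equal(null$slope, 0)

  prop <- sensitivity_slope(tibble::tibble(dtemp = c(-1, 0, 1),
                                           dvalue = c(-2, 0, 2)))
  expect_equal(prop$slope, 2)
  expect_equal(prop$r, 1)

  hand <- sensitivity_slope(tibble::tibble(dtemp = c(-1.5, -0.5, 0.5, 1.5),
                                           dvalue = c(-2, 1, -1, 2)))
  expect_equal(hand$slope, 1.0)  # Sxy = 5, Sxx = 5

  degen <- sensitivity_slope(tibble::tibble(dtemp = c(1, 1, 1),
                                            dvalue = c(1, 2, 3)))
  expect_true(is.na(degen$slope))

  # listwise deletion of missing pairs
  miss <- sensitivity_slope(tibble::tibble(dtemp = c(-1, 0, 1, 2, NA),
                                           dvalue = c(-2, 0, 2, NA, 5)))
  expect_equal(miss$n_years, 3L)
  expect_equal(miss$slope, 2)
})

test_that("detrended slope equals the joint-regression temperature coefficient", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(6:25, 1)
    yrs <- 2000:(2000 + n - 1)
    temp <- rnorm(n) + 0.05 * yrs
    val <- 5 + 1.3 * temp - 0.2 * (yrs - 2000) + rnorm(n)
    joint <- unname(coef(lm(val ~ temp + yrs))["temp"])
    pr <- anomaly_pairs(tibble::tibble(cell_id = 1, year = yrs,
                                       t = temp, v = val),
                        temp = t, value = v)
    ours <- sensitivity_slope(pr)$slope
    expect_equal(ours, joint, tolerance = 1e-9)
  }
})

test_that("gridwise estimation recovers truth and applies the year filter", {
  tr <- make_truth(5, n_lat = 6, n_lon = 6, years = 2000:2009,
                   scenario = "two-region", noise_sd_daily = c(pm = 0, o3 = 0))
  seas <- seasonal_joined(tr)
  map <- gridwise_sensitivity(seas, value = value, temp = temp,
                              unit = cell_id, coords = tr$grid)
  joined <- dplyr::left_join(map, tr$grid[, c("cell_id", "beta_pm")],
                             by = c(unit_id = "cell_id"))
  expect_lt(max(abs(joined$slope - joined$beta_pm)), 1e-9)
  expect_equal(nrow(map), 36)

  # a cell with only 2 complete years is missing in the output
  seas2 <- dplyr::filter(seas, !(cell_id == 1 & year > 2001))
  map2 <- gridwise_sensitivity(seas2, value = value, temp = temp,
                               unit = cell_id)
  expect_true(is.na(map2$slope[map2$unit_id == 1]))

  # gridwise slope agrees with lm() per cell on noisy data
  trn <- flat_truth(seed = 6, n = 5, years = 2000:2008, noise = 3)
  seasn <- seasonal_joined(trn)
  mapn <- gridwise_sensitivity(seasn, value = value, temp = temp,
                               unit = cell_id)
  one <- dplyr::filter(seasn, cell_id == 7)
  ref <- unname(coef(lm(value ~ temp + year, data = one))["temp"])
  expect_equal(mapn$slope[mapn$unit_id == 7], ref, tolerance = 1e-9)
})

test_that("negative slopes clamp to zero for exposure analysis, idempotently", {
  m <- new_map <- tibble::tibble(lat = 1, lon = 1:3,
                                 slope = c(-0.3, 1.2, 0),
                                 p_value = c(0.5, 0.01, 0.9))
  out <- prepare_exposure_map(m)
  expect_equal(out$slope, c(0, 1.2, 0))
  expect_equal(out$p_value, m$p_value)
  expect_identical(prepare_exposure_map(out), out)
  allneg <- prepare_exposure_map(tibble::tibble(slope = c(-1, -2)))
  expect_equal(allneg$slope, c(0, 0))
})

test_that("great-circle distances match the haversine oracle and metric axioms", {
  expect_equal(haversine_km(40, -100, 40, -100), 0)
  d <- haversine_km(40, -100, 40, -99.7)
  expect_equal(d, 25.6, tolerance = 0.01)
  expect_lt(d, 30)
  skip_if_not_installed("geosphere")
  ref <- geosphere::distHaversine(c(-100, 40), c(-99.7, 40), r = 6371000) / 1000
  expect_equal(d, ref, tolerance = 1e-9)

  set.seed(31)
  for (i in 1:20) {
    p <- matrix(c(runif(3, 25, 50), runif(3, -120, -70)), ncol = 2)
    d12 <- haversine_km(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    d21 <- haversine_km(p[2, 1], p[2, 2], p[1, 1], p[1, 2])
    d13 <- haversine_km(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    d23 <- haversine_km(p[2, 1], p[2, 2], p[3, 1], p[3, 2])
    expect_equal(d12, d21)
    expect_lte(d13, d12 + d23 + 1e-9)
  }
})

test_that("station co-location averages in-radius stations datewise", {
  dts <- as.Date("2000-06-01") + 0:2
  poll <- tibble::tibble(site_id = "p1", lat = 40, lon = -100,
                         date = dts, value = c(10, 11, 12))
  temps <- dplyr::bind_rows(
    tibble::tibble(site_id = "t1", lat = 40, lon = -100, date = dts,
                   value = c(10, 10, 10)),
    tibble::tibble(site_id = "t2", lat = 40, lon = -99.7, date = dts,
                   value = c(20, 20, 20)),
    tibble::tibble(site_id = "t3", lat = 45, lon = -90, date = dts,
                   value = c(99, 99, 99))
  )
  out <- colocate_station_pairs(poll, temps, radius_km = 30)
  expect_equal(nrow(out), 3)
  expect_equal(out$temp, c(15, 15, 15))   # far station excluded
  expect_equal(unique(out$n_temp_stations), 2L)

  far <- tibble::tibble(site_id = "p2", lat = 30, lon = -80,
                        date = dts, value = 1:3)
  expect_message(out2 <- colocate_station_pairs(far, temps, radius_km = 30),
                 "dropped")
  expect_equal(nrow(out2), 0)
})

test_that("grid co-location returns cell series, averages ties, drops distant sites", {
  tr <- flat_truth(years = 2000:2002)
  sim <- simulate_fields(tr, frequency = "daily")
  coords <- tr$grid[, c("cell_id", "lat", "lon")]
  at_center <- tibble::tibble(site_id = "s1", lat = coords$lat[1],
                              lon = coords$lon[1])
  out <- extract_colocated_grid(sim$pollutant, at_center, coords, pm25,
                                radius_km = 5)
  ref <- dplyr::filter(sim$pollutant, cell_id == coords$cell_id[1])
  expect_equal(out$value, ref$pm25)

  # equidistant between two centers within radius: mean of the two series
  mid <- tibble::tibble(site_id = "m",
                        lat = coords$lat[1],
                        lon = (coords$lon[1] + coords$lon[2]) / 2)
  out2 <- extract_colocated_grid(sim$pollutant, mid, coords, pm25,
                                 radius_km = 30)
  # brute-force mean over the in-radius cells
  dists <- haversine_km(mid$lat, mid$lon, coords$lat, coords$lon)
  near <- coords$cell_id[dists <= 30]
  ref2 <- dplyr::filter(sim$pollutant, cell_id %in% near) |>
    dplyr::group_by(date) |> dplyr::summarise(v = mean(pm25), .groups = "drop")
  expect_equal(unique(out2$n_cells), length(near))
  expect_equal(out2$value, ref2$v)

  # radius smaller than half the spacing with the site between centers
  expect_warning(
    out3 <- extract_colocated_grid(sim$pollutant, mid, coords, pm25,
                                   radius_km = 5),
    "dropped")
  expect_equal(nrow(out3), 0)
})
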