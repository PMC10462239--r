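test_that("weighted quantiles follow the left-continuous inverse CDF", {
  eq <- weighted_quantiles(c(1, 2, 3, 4), rep(1, 4), probs = 0.5)
  expect_equal(eq$quantile, 2)

  skewed <- weighted_quantiles(c(1, 2, 3), c(1, 1, 8), probs = 0.5)
  expect_equal(skewed$quantile, 3)

  single <- weighted_quantiles(5, 2, probs = c(0.05, 0.5, 0.95))
  expect_equal(single$quantile, c(5, 5, 5))

  expect_error(weighted_quantiles(1:3, c(0, 0, 0)), "zero")
  expect_error(weighted_quantiles(1:3, rep(1, 3), probs = 1.2), "\\(0, 1\\)")

  # random vectors against the brute-force oracle, equal and random weights
  set.seed(51)
  for (i in 1:25) {
    v <- rnorm(sample(5:40, 1))
    w <- runif(length(v), 0.1, 2)
    for (p in c(0.05, 0.25, 0.5, 0.75, 0.95)) {
      expect_equal(weighted_quantiles(v, w, probs = p)$quantile,
                   bf_wquant(v, w, p))
      expect_equal(weighted_quantiles(v, rep(1, length(v)), probs = p)$quantile,
                   bf_wquant(v, rep(1, length(v)), p))
    }
  }
})

test_that("weighted quantiles are nondecreasing in probability", {
  set.seed(52)
  v <- rnorm(100); w <- runif(100)
  q <- weighted_quantiles(v, w)
  expect_true(all(diff(q$quantile) >= 0))
})

test_that("population alignment conserves totals and maps nearest centers", {
  tr <- flat_truth()
  map <- tibble::tibble(lat = tr$grid$lat, lon = tr$grid$lon,
                        slope = runif(nrow(tr$grid)))
  pop <- simulate_population(tr, n_clusters = 2, seed = 3)

  identical_grid <- align_population(pop, map)
  expect_equal(identical_grid$weight, pop$count)

  # offset by less than half a cell: same assignment
  shifted <- dplyr::mutate(pop, lat = lat + tr$cell_deg / 4,
                           lon = lon - tr$cell_deg / 4)
  expect_equal(align_population(shifted, map)$weight, identical_grid$weight)

  # random offsets still conserve the total
  set.seed(53)
  jitter <- dplyr::mutate(pop, lat = lat + runif(dplyr::n(), -0.4, 0.4),
                          lon = lon + runif(dplyr::n(), -0.4, 0.4))
  out <- align_population(jitter, map)
  expect_equal(sum(out$weight), sum(pop$count), tolerance = 1e-9)

  far <- dplyr::mutate(pop, lat = lat + 90)
  expect_error(align_population(far, map), "disjoint")
})

test_that("exceedance fractions match exhaustive oracles and are monotone", {
  set.seed(54)
  map <- tibble::tibble(lat = runif(200, 30, 45), lon = runif(200, -110, -80),
                        slope = rnorm(200, 1, 0.8))
  map <- prepare_exposure_map(map)
  w <- runif(200)
  expect_equal(fraction_above(map, min(map$slope) - 1, weights = w), 1.0)
  expect_equal(fraction_above(map, max(map$slope) + 1, weights = w), 0.0)
  for (thr in c(0, 0.5, 1, 1.5)) {
    expect_equal(fraction_above(map, thr, weights = w),
                 sum(w[map$slope >= thr]) / sum(w))
  }
  thrs <- seq(-0.5, 3, by = 0.1)
  fr <- vapply(thrs, function(t) fraction_above(map, t, weights = w), double(1))
  expect_true(all(diff(fr) <= 1e-12))
})

test_that("the 75th-percentile threshold captures about a quarter of the weight", {
  set.seed(55)
  map <- tibble::tibble(lat = runif(500, 30, 45), lon = runif(500, -110, -80),
                        slope = rlnorm(500, 0, 0.5))
  w <- runif(500)
  map$weight <- w
  thr <- derive_threshold(map)
  expect_equal(thr, bf_wquant(map$slope, w, 0.75))
  fr <- fraction_above(map, thr, weights = w)
  expect_gte(fr, 0.20)
  expect_lte(fr, 0.30)
  # operational override passes straight through
  expect_equal(derive_threshold(map, override = 1), 1)
})

test_that("urban classification boundary sits exactly at the cutoff", {
  pop <- tibble::tibble(cell_id = 1:3, density = c(400, 399.9, 0))
  out <- urban_mask(pop)
  expect_equal(out$urban, c(TRUE, FALSE, FALSE))
  allzero <- urban_mask(tibble::tibble(cell_id = 1:4, density = rep(0, 4)))
  expect_false(any(allzero$urban))
})

test_that("urban/nonurban stratification recovers contrasting truths", {
  set.seed(56)
  yrs <- 2000:2009
  dt <- rnorm(10, sd = 0.6)
  cells <- 1:20
  urban_cells <- 1:8
  anoms <- tidyr::expand_grid(unit_id = cells, year = yrs) |>
    dplyr::mutate(dtemp = dt[year - 1999] - mean(dt),
                  dvalue = ifelse(unit_id %in% urban_cells, 3.0, 1.0) * dtemp)
  mask <- tibble::tibble(cell_id = cells, urban = cells %in% urban_cells)
  out <- stratified_sensitivity(anoms, mask)
  expect_equal(out$slope[out$stratum == "urban"], 3.0, tolerance = 1e-9)
  expect_equal(out$slope[out$stratum == "nonurban"], 1.0, tolerance = 1e-9)

  # uniform truth: equal strata
  uni <- dplyr::mutate(anoms, dvalue = 2 * dtemp)
  out_u <- stratified_sensitivity(uni, mask)
  expect_equal(out_u$slope[1], out_u$slope[2], tolerance = 1e-9)

  # all cells urban: nonurban stratum flagged undefined
  all_urb <- tibble::tibble(cell_id = cells, urban = TRUE)
  out_a <- stratified_sensitivity(anoms, all_urb)
  expect_false(out_a$defined[out_a$stratum == "nonurban"])
  expect_true(is.na(out_a$slope[out_a$stratum == "nonurban"]))
})

test_that("exposure distribution rows are internally consistent", {
  set.seed(57)
  tr <- flat_truth()
  map <- tibble::tibble(lat = tr$grid$lat, lon = tr$grid$lon,
                        slope = rlnorm(nrow(tr$grid), 0, 0.4))
  pop <- simulate_population(tr, seed = 2)
  prepared <- align_population(pop, prepare_exposure_map(map))
  row <- exposure_distribution(prepared, "population", window = "pm_jja",
                               period = "full")
  qs <- unlist(row[, c("q05", "q25", "q50", "q75", "q95")])
  expect_true(all(diff(qs) >= 0))
  expect_gte(row$fraction_above, 0)
  expect_lte(row$fraction_above, 1)
  expect_equal(row$threshold, unname(qs["q75"]))
  area_row <- exposure_distribution(prepared, "area")
  expect_equal(area_row$total_weight, sum(cos(prepared$lat * pi / 180)))
})
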