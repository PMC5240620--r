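test_that("scenario selection keeps exactly the positive-probability pairs", {
  m <- default_scenario_matrix()
  sel <- select_scenarios(m)
  expect_equal(nrow(sel), 15L)
  expect_false(any(sel$ssp == 1 & sel$rcp == 8.5))
  # SSP-major stable order
  expect_true(!is.unsorted(sel$ssp))
  expect_equal(sel$ssp[1:3], c(1L, 1L, 1L))
  expect_equal(sel$rcp[1:3], c(2.6, 4.5, 6.0))
  # all-zero matrix: empty selection
  empty <- select_scenarios(scenario_matrix(matrix(0, 5, 4)))
  expect_equal(nrow(empty), 0L)
})

test_that("annualization interpolates linearly and reproduces input steps", {
  s <- make_series(1L, c(2000L, 2010L), list(c(100, 200)), list(c(0.4, 0.5)))
  a <- annualize(s)
  expect_equal(a$total_population[a$year == 2005], 150)
  expect_equal(a$total_population[a$year == 2000], 100)
  expect_equal(a$total_population[a$year == 2010], 200)
  s2 <- make_series(1L, c(2000L, 2005L), list(c(100, 100)), list(c(0.40, 0.50)))
  a2 <- annualize(s2)
  expect_equal(a2$urban_share[a2$year == 2003], 0.46)
  expect_error(annualize(s, years = 1999:2005), "outside")
  expect_error(annualize(scenario_series(data.frame(
    country_id = 1L, year = 2000L, total_population = 1, urban_share = 0))),
    ">= 2 time points")
})

test_that("allotment is proportional within strata", {
  g <- tiny_geometry(R = 2L, ncr = 1L, ncc = 1L)
  countries <- country_raster(g, matrix(1L, 2, 2))
  prev2 <- fine_grid(g, matrix(c(1, 9, 3, 6), 2, 2))
  mask2 <- build_urban_mask(prev2, coarse_grid(g, matrix(0.75, 1, 1)))
  # urban = {9,6,3}; rural = {1}; choose urban share so target is 100
  series <- make_series(1L, c(2000L, 2001L), list(c(120, 120)),
                        list(c(100 / 120, 100 / 120)))
  out <- allot_population(prev2, mask2, countries, series, 2000L)
  expect_equal(out$values[2, 1], 100 * 9 / 18)  # weight 9
  expect_equal(out$values[2, 2], 100 * 6 / 18)  # weight 6
  expect_equal(out$values[1, 2], 100 * 3 / 18)  # weight 3
  expect_equal(out$values[1, 1], 20)            # whole rural stratum
  expect_equal(sum(out$values[out$valid_mask]), 120)
})

test_that("pairwise pixel ratios within a stratum survive allotment", {
  for (s in 1:10) {
    g <- tiny_geometry(R = 5L, ncr = 2L, ncc = 2L)
    prev <- random_fine_grid(g, seed = 200 + s)
    ids <- matrix(sample(1:3, 100, replace = TRUE), 10, 10)
    countries <- country_raster(g, ids)
    set.seed(300 + s)
    frac <- matrix(runif(4, 0.1, 0.9), 2, 2)
    mask <- build_urban_mask(prev, coarse_grid(g, frac))
    series <- make_series(1:3, c(2000L, 2001L),
                          list(c(500, 600), c(800, 900), c(100, 150)),
                          list(c(0.5, 0.5), c(0.3, 0.3), c(0.8, 0.8)))
    out <- allot_population(prev, mask, countries, series, 2000L)
    for (cid in 1:3) for (urb in c(TRUE, FALSE)) {
      sel <- countries$ids == cid & mask$urban == urb & out$valid_mask
      w <- prev$values[sel]; v <- out$values[sel]
      keep <- w > 0
      if (sum(keep) >= 2) {
        ratio <- v[keep] / w[keep]
        expect_lt(diff(range(ratio)) / max(ratio), 1e-12)
      }
    }
    # per-country conservation
    agg <- aggregate_by_region(out, countries)
    expect_equal(agg$population, c(500, 800, 100), tolerance = 1e-12)
  }
})

test_that("two countries sharing one coarse cell conserve their own totals", {
  w <- two_country_shared_cell_world()
  mask <- build_urban_mask(w$pop, coarse_grid(w$geometry, matrix(0.5, 1, 1)))
  series <- make_series(1:2, c(2000L, 2001L),
                        list(c(1000, 1100), c(2000, 2100)),
                        list(c(0.5, 0.5), c(0.5, 0.5)))
  out <- allot_population(w$pop, mask, w$countries, series, 2000L)
  # per-pixel loop oracle per country
  for (cid in 1:2) {
    sel <- w$countries$ids == cid
    expect_equal(sum(out$values[sel]), c(1000, 2000)[cid], tolerance = 1e-12)
  }
})

test_that("zero-weight strata receive their target uniformly", {
  g <- tiny_geometry(R = 2L, ncr = 1L, ncc = 1L)
  prev <- fine_grid(g, matrix(c(5, 0, 4, 0), 2, 2))
  mask <- build_urban_mask(prev, coarse_grid(g, matrix(0.5, 1, 1)))
  countries <- country_raster(g, matrix(1L, 2, 2))
  series <- make_series(1L, c(2000L, 2001L), list(c(100, 100)),
                        list(c(0.6, 0.6)))
  out <- allot_population(prev, mask, countries, series, 2000L)
  # rural stratum (the two zero pixels) gets 40 spread uniformly
  expect_equal(out$values[2, 1], 20)
  expect_equal(out$values[2, 2], 20)
  expect_equal(sum(out$values), 100)
})

test_that("missing or negative series entries are rejected with names", {
  g <- tiny_geometry(R = 2L, ncr = 1L, ncc = 1L)
  # interleave values so each country keeps one urban and one rural pixel
  prev <- fine_grid(g, matrix(c(4, 1, 2, 3), 2, 2))
  mask <- build_urban_mask(prev, coarse_grid(g, matrix(0.5, 1, 1)))
  countries <- country_raster(g, matrix(c(1L, 1L, 2L, 2L), 2, 2))
  series <- make_series(1L, c(2000L, 2001L), list(c(10, 10)), list(c(0.5, 0.5)))
  expect_error(allot_population(prev, mask, countries, series, 2000L),
               "country id\\(s\\): 2")
  series2 <- make_series(1:3, c(2000L, 2001L),
                         list(c(10, 10), c(5, 5), c(7, 7)),
                         list(c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5)))
  expect_warning(allot_population(prev, mask, countries, series2, 2000L),
                 "absent from the raster")
})

# In these two fixtures the country urban share sits above the urban
# pixels' mass share, so the urban stratum is scaled up relative to the
# rural one, the top-k set is preserved, and the mask is stable from the
# first year on; with a stable mask, constant inputs are a fixed point.
test_that("constant series and fractions give a fixed point across years", {
  set.seed(3)
  R <- 6L
  g <- grid_geometry(0, 0, 1, R, R, R)
  pop <- fine_grid(g, matrix(runif(36, 1, 50), R, R))
  countries <- country_raster(g, matrix(1L, R, R))
  fr <- lapply(2000:2006, function(y) coarse_grid(g, matrix(0.4, 1, 1)))
  names(fr) <- 2000:2006
  series <- make_series(1L, c(2000L, 2006L), list(c(900, 900)),
                        list(c(0.8, 0.8)))
  up <- baseline_unique_population(pop, list(cbind(c(0, 6), c(-3.1, -3.4))))
  run <- project_scenario(up, fr, countries, annualize(series), 2000:2006)
  for (y in 2001:2006)
    expect_equal(run$grids[[as.character(y)]]$values,
                 run$grids[["2000"]]$values, tolerance = 1e-12)
})

test_that("doubling country totals doubles every pixel under constant fractions", {
  set.seed(9)
  R <- 6L
  g <- grid_geometry(0, 0, 1, R, R, R)
  pop <- fine_grid(g, matrix(runif(36, 1, 50), R, R))
  countries <- country_raster(g, matrix(1L, R, R))
  fr <- lapply(2000:2001, function(y) coarse_grid(g, matrix(0.5, 1, 1)))
  names(fr) <- 2000:2001
  series <- make_series(1L, c(2000L, 2001L), list(c(700, 1400)),
                        list(c(0.8, 0.8)))
  up <- baseline_unique_population(pop, list(cbind(c(0, 6), c(-2.6, -2.9))))
  run <- project_scenario(up, fr, countries, annualize(series), 2000:2001)
  expect_equal(run$grids[["2001"]]$values, 2 * run$grids[["2000"]]$values,
               tolerance = 1e-12)
})

test_that("raising a cell's urban fraction adds exactly the rounded pixel count", {
  g <- tiny_geometry(R = 4L, ncr = 2L, ncc = 1L)
  pop <- random_fine_grid(g, seed = 31)
  countries <- country_raster(g, matrix(1L, 8, 4))
  f0 <- matrix(c(0.25, 0.25), 2, 1)
  f1 <- matrix(c(0.50, 0.25), 2, 1)
  fr <- list("2000" = coarse_grid(g, f0), "2001" = coarse_grid(g, f1))
  series <- make_series(1L, c(2000L, 2001L), list(c(1000, 1000)),
                        list(c(0.3, 0.3)))
  up <- baseline_unique_population(pop, list(cbind(c(0, 4), c(-4.2, -3.7))))
  run <- project_scenario(up, fr, countries, annualize(series), 2000:2001)
  expect_equal(run$urban_pixels[2] - run$urban_pixels[1], round(0.25 * 16))
})

test_that("outputs for year t ignore perturbations of future inputs", {
  w <- two_country_shared_cell_world(R = 6L, seed = 13L)
  years <- 2000:2004
  fr <- lapply(years, function(y) coarse_grid(w$geometry, matrix(0.4, 1, 1)))
  names(fr) <- years
  totals <- list(c(900, 950, 1000, 1050, 1100), c(1500, 1520, 1540, 1560, 1580))
  series <- annualize(make_series(1:2, years, totals,
                                  list(rep(0.4, 5), rep(0.6, 5))))
  up <- baseline_unique_population(w$pop, list(cbind(c(0, 6), c(-3.1, -3.4))))
  run1 <- project_scenario(up, fr, w$countries, series, years)
  # perturb the future: different 2004 fraction and totals
  fr2 <- fr
  fr2[["2004"]] <- coarse_grid(w$geometry, matrix(0.9, 1, 1))
  series2 <- series
  series2$total_population[series2$year == 2004] <-
    series2$total_population[series2$year == 2004] * 3
  run2 <- suppressWarnings(
    project_scenario(up, fr2, w$countries, series2, years))
  for (y in 2000:2003)
    expect_identical(run1$grids[[as.character(y)]]$values,
                     run2$grids[[as.character(y)]]$values)
  expect_false(identical(run1$grids[["2004"]]$values,
                         run2$grids[["2004"]]$values))
})

test_that("projection refuses to start with missing years", {
  w <- two_country_shared_cell_world()
  fr <- list("2000" = coarse_grid(w$geometry, matrix(0.4, 1, 1)))
  series <- annualize(make_series(1:2, c(2000L, 2001L),
                                  list(c(1, 1), c(1, 1)),
                                  list(c(0.5, 0.5), c(0.5, 0.5))))
  up <- w$pop
  expect_error(project_scenario(up, fr, w$countries, series, 2000:2001),
               "missing urban-fraction")
  fr[["2001"]] <- fr[["2000"]]
  series3 <- series[series$year == 2000, ]
  class(series3) <- class(series)
  expect_error(project_scenario(up, fr, w$countries, series3, 2000:2001),
               "misses year 2001")
})

test_that("invalid pixels stay invalid and values stay non-negative across a run", {
  spec <- synth_spec(seed = 21, n_countries = 3L, water_fraction = 0.2)
  w <- generate_world(spec)
  up <- baseline_unique_population(w$baseline, w$roads)
  series <- annualize(w$series, years = 2000:2005)
  run <- project_scenario(up, w$fractions, w$countries, series, 2000:2005)
  for (g in run$grids) {
    expect_identical(g$valid_mask, w$baseline$valid_mask)
    expect_true(all(g$values[g$valid_mask] >= 0))
  }
})
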