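test_that("road distances match a closed form for a vertical road", {
  g <- grid_geometry(0, 0, 1, 1L, 5L, 5L)
  road <- cbind(c(2, 2), c(0, -5))        # along lon = 2
  d <- distance_to_roads(list(road), g)
  ctr <- center_matrices(g)
  expect_equal(d$values, abs(ctr$lon - 2))
  # a pixel whose center lies on a road vertex has distance zero
  road2 <- cbind(c(0.5, 3), c(-0.5, -4))
  d2 <- distance_to_roads(list(road2), g)
  expect_equal(d2$values[1, 1], 0)
})

test_that("road distances agree with a brute-force minimisation oracle", {
  g <- grid_geometry(0, 0, 1, 1L, 5L, 5L)
  set.seed(42)
  roads <- list(cbind(runif(2, 0, 5), runif(2, -5, 0)),
                cbind(runif(3, 0, 5), runif(3, -5, 0)))
  d <- distance_to_roads(roads, g)
  ctr <- center_matrices(g)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(d$values[i, j],
                 oracle_point_to_lines(ctr$lon[i, j], ctr$lat[i, j], roads),
                 tolerance = 1e-9)
  }
})

test_that("an empty road set is rejected", {
  expect_error(distance_to_roads(list(), tiny_geometry()), "empty road set")
})

test_that("centers of gravity equal the population-weighted coordinate mean", {
  g <- tiny_geometry(R = 3L, ncr = 1L, ncc = 1L)
  # point mass: COG is that pixel's center
  v <- matrix(0, 3, 3); v[2, 3] <- 11
  cog <- compute_cogs(fine_grid(g, v))
  expect_equal(cog$lon, 2.5)
  expect_equal(cog$lat, -1.5)
  expect_true(cog$weighted)
  # uniform: COG is the mean of pixel centers (cell center by symmetry)
  cog <- compute_cogs(fine_grid(g, matrix(4, 3, 3)))
  expect_equal(cog$lon, 1.5)
  expect_equal(cog$lat, -1.5)
  # weights 1..9: direct weighted-mean oracle
  w <- matrix(1:9, 3, 3)
  cog <- compute_cogs(fine_grid(g, w))
  ctr <- center_matrices(g)
  expect_equal(cog$lon, sum(w * ctr$lon) / sum(w))
  expect_equal(cog$lat, sum(w * ctr$lat) / sum(w))
  # zero population falls back to the cell's geometric center
  cog <- compute_cogs(fine_grid(g, matrix(0, 3, 3)))
  expect_equal(cog$lon, 1.5)
  expect_equal(cog$lat, -1.5)
  expect_false(cog$weighted)
})

test_that("distance to COG is zero at the COG and grows away from a point mass", {
  g <- tiny_geometry(R = 3L, ncr = 1L, ncc = 1L)
  v <- matrix(0, 3, 3); v[2, 2] <- 5
  pop <- fine_grid(g, v)
  d <- distance_to_cog(compute_cogs(pop), g)
  expect_equal(d$values[2, 2], 0)
  expect_true(all(d$values[-5] > 0))
  # hand check against the weighted-mean COG on a 3x3 cell
  w <- matrix(c(2, 0, 1, 0, 0, 0, 3, 0, 0), 3, 3)
  pop <- fine_grid(g, w)
  cog <- compute_cogs(pop)
  ctr <- center_matrices(g)
  d <- distance_to_cog(cog, g)
  expect_equal(d$values,
               sqrt((ctr$lon - cog$lon)^2 + (ctr$lat - cog$lat)^2))
})

test_that("inverse rescaling hits the published bounds and reverses rank order", {
  g <- grid_geometry(0, 0, 1, 1L, 2L, 1L)
  d <- fine_grid(g, matrix(c(0, 1), 2, 1))
  r <- inverse_rescale(d)
  # nearest pixel gets the upper bound, farthest the lower
  expect_equal(r$values[1, 1], 1.1e-5)
  expect_equal(r$values[2, 1], 1.0e-5)
  # random layer: output rank order is exactly the reversed distance order
  g10 <- grid_geometry(0, 0, 1, 1L, 10L, 10L)
  set.seed(9)
  dv <- matrix(runif(100, 0, 8), 10, 10)
  r <- inverse_rescale(fine_grid(g10, dv))
  expect_identical(rank(-r$values), rank(dv))
  expect_equal(min(r$values), 1.0e-5)
  expect_equal(max(r$values), 1.1e-5)
  # degenerate layers are rejected
  expect_error(inverse_rescale(fine_grid(g10, matrix(3, 10, 10))), "identical")
})

test_that("unique population preserves large-gap orderings and bounds the perturbation", {
  g <- tiny_geometry(R = 4L, ncr = 1L, ncc = 1L)
  set.seed(11)
  pop <- random_fine_grid(g, seed = 11)
  road <- list(cbind(c(0, 4), c(-1.3, -2.2)))
  up <- baseline_unique_population(pop, road)
  expect_s3_class(up, "unique_population")
  expect_lte(up$perturbation_bound, 2.2e-5 + 1e-12)
  # removing the perturbation recovers the input to within the bound
  expect_lte(max(abs(up$values - pop$values)), up$perturbation_bound)
  # pixels separated by more than the bound never swap rank
  for (s in 1:20) {
    pop2 <- random_fine_grid(g, seed = 100 + s)
    up2 <- baseline_unique_population(pop2, road)
    v0 <- pop2$values[pop2$valid_mask]
    v1 <- up2$values[up2$valid_mask]
    pairs <- which(outer(v0, v0, function(a, b) a - b) > 2.2e-5, arr.ind = TRUE)
    expect_true(all(v1[pairs[, 1]] > v1[pairs[, 2]]))
  }
})

test_that("equal populations become distinct through the perturbations", {
  g <- tiny_geometry(R = 3L, ncr = 1L, ncc = 1L)
  pop <- fine_grid(g, matrix(5, 3, 3))
  # road placed asymmetrically, so no two pixels share both distances
  road <- list(cbind(c(0.2, 2.9), c(-0.1, -2.2)))
  up <- baseline_unique_population(pop, road)
  v <- up$values[up$valid_mask]
  expect_equal(length(unique(v)), length(v))
  # zero population: values are pure perturbations in [2.0e-5, 2.2e-5]
  up0 <- baseline_unique_population(fine_grid(g, matrix(0, 3, 3)), road)
  v0 <- up0$values[up0$valid_mask]
  expect_true(all(v0 >= 2.0e-5 & v0 <= 2.2e-5))
})

test_that("urban mask selects the top-k pixels per coarse cell", {
  g <- tiny_geometry(R = 2L, ncr = 1L, ncc = 1L)
  up <- fine_grid(g, matrix(c(5, 2, 3, 1), 2, 2))
  mask <- build_urban_mask(up, coarse_grid(g, matrix(0.5, 1, 1)))
  expect_equal(sum(mask$urban), 2L)
  expect_true(mask$urban[1, 1])            # value 5
  expect_true(mask$urban[1, 2])            # value 3
  expect_false(any(mask$urban[2, ]))       # values 2 and 1 stay non-urban
  # endpoints: fraction 0 -> none; fraction 1 -> all valid pixels
  expect_equal(sum(build_urban_mask(up, coarse_grid(g, matrix(0, 1, 1)))$urban), 0L)
  expect_equal(sum(build_urban_mask(up, coarse_grid(g, matrix(1, 1, 1)))$urban), 4L)
  # fraction 0.35 on a 3x3 cell: k = round(3.15) = 3
  g3 <- tiny_geometry(R = 3L, ncr = 1L, ncc = 1L)
  set.seed(2)
  v <- matrix(runif(9), 3, 3)
  m3 <- build_urban_mask(fine_grid(g3, v), coarse_grid(g3, matrix(0.35, 1, 1)))
  expect_equal(sum(m3$urban), 3L)
  expect_identical(sort(which(m3$urban)), sort(oracle_top_k(as.vector(v), 3L)))
  # fractions outside [0,1] are rejected
  expect_error(build_urban_mask(up, coarse_grid(g, matrix(1.2, 1, 1))), "\\[0, 1\\]")
})

test_that("urban counts are capped at land pixels and sum to rounded targets", {
  g <- tiny_geometry(R = 3L, ncr = 2L, ncc = 2L)
  set.seed(5)
  mask_land <- matrix(TRUE, 6, 6)
  mask_land[1:3, 1:3] <- FALSE             # first cell fully water
  mask_land[4, 4] <- FALSE                 # one water pixel elsewhere
  up <- random_fine_grid(g, seed = 5, mask = mask_land)
  frac <- matrix(c(0.8, 0.5, 1.0, 0.25), 2, 2)   # column-major fill
  m <- build_urban_mask(up, coarse_grid(g, frac))
  counts <- urban_counts(m)
  # k from the full R^2 area, then capped at valid pixels
  expect_equal(counts[1, 1], 0)                   # fraction 0.8 but no land
  expect_equal(counts[2, 1], 5)      # 4.5 rounds away from zero: 5 of 9
  expect_equal(counts[1, 2], 9)                   # fraction 1: all 9 land
  expect_equal(counts[2, 2], round(0.25 * 9))     # 2 of 8 land pixels
  expect_true(all(!(m$urban & !mask_land)))             # never urbanise water
  # counting invariant: total equals the sum of per-cell capped targets
  expect_equal(sum(m$urban), sum(counts))
})

test_that("half counts round away from zero, not to even", {
  g <- tiny_geometry(R = 2L, ncr = 1L, ncc = 1L)
  up <- fine_grid(g, matrix(c(4, 3, 2, 1), 2, 2))
  # 0.125 * 4 = 0.5 -> 1 urban pixel (banker's rounding would give 0)
  m <- build_urban_mask(up, coarse_grid(g, matrix(0.125, 1, 1)))
  expect_equal(sum(m$urban), 1L)
})

test_that("identical inputs give bit-identical masks", {
  g <- tiny_geometry(R = 4L, ncr = 2L, ncc = 2L)
  up <- random_fine_grid(g, seed = 77)
  f <- coarse_grid(g, matrix(c(0.3, 0.6, 0.1, 0.9), 2, 2))
  m1 <- build_urban_mask(up, f)
  m2 <- build_urban_mask(up, f)
  expect_identical(m1$urban, m2$urban)
})
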