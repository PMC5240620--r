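# Shared fixtures and independent oracles.

# tiny geometry: unit-degree pixels so coordinates are easy to reason about
tiny_geometry <- function(R = 3L, ncr = 2L, ncc = 2L, cell = 1) {
  grid_geometry(0, 0, cell, R, ncr * R, ncc * R)
}

# a fine grid with reproducible random positive values
random_fine_grid <- function(geometry, seed = 1L, mask = NULL) {
  set.seed(seed)
  v <- matrix(runif(geometry$n_fine_rows * geometry$n_fine_cols, 0, 100),
              geometry$n_fine_rows, geometry$n_fine_cols)
  fine_grid(geometry, v, mask)
}

# brute-force distance from one point to a polyline set: 1-D minimisation
# over the segment parameter, independent of the closed-form projection
oracle_point_to_lines <- function(px, py, roads) {
  best <- Inf
  for (line in roads) {
    for (i in seq_len(nrow(line) - 1L)) {
      f <- function(t) {
        qx <- line[i, 1] + t * (line[i + 1, 1] - line[i, 1])
        qy <- line[i, 2] + t * (line[i + 1, 2] - line[i, 2])
        sqrt((px - qx)^2 + (py - qy)^2)
      }
      opt <- optimize(f, c(0, 1), tol = 1e-12)
      best <- min(best, opt$objective, f(0), f(1))
    }
  }
  best
}

# brute-force best-k subset of values (returns indices of the max-total set)
oracle_top_k <- function(values, k) {
  if (k == 0L) return(integer(0))
  combos <- utils::combn(length(values), k)
  sums <- colSums(matrix(values[combos], nrow = k))
  combos[, which.max(sums)]
}

# two countries sharing every coarse cell: left/right vertical split of a
# single-coarse-cell-wide world would put both in one cell; here countries
# interleave by row so every coarse cell contains both
two_country_shared_cell_world <- function(R = 4L, seed = 3L) {
  g <- tiny_geometry(R = R, ncr = 1L, ncc = 1L)
  set.seed(seed)
  pop <- matrix(runif(R * R, 1, 50), R, R)
  ids <- matrix(rep_len(c(1L, 2L), R * R), R, R)
  list(geometry = g,
       pop = fine_grid(g, pop),
       countries = country_raster(g, ids))
}

make_series <- function(ids, years, totals, shares) {
  scenario_series(expand_series(ids, years, totals, shares))
}

expand_series <- function(ids, years, totals, shares) {
  do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(country_id = ids[i], year = years,
               total_population = totals[[i]],
               urban_share = shares[[i]])
  }))
}
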