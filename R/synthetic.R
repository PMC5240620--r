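#' Specification for a synthetic toy world
#'
#' Describes a complete, internally consistent miniature of the real
#' inputs: a clustered non-negative baseline population on a fine
#' lattice nested inside coarse cells, a handful of countries tiling the
#' land area, a road network crossing them, monotone-trending urban
#' fractions consistent with the population clusters, and smooth
#' country-level population trajectories with urban shares at
#' five-year steps.  Every generated world satisfies the input
#' preconditions of the ranking, allotment and I/O operations, so the
#' whole pipeline can be exercised without any external download.
#'
#' Defaults give the test-scale world (2 x 2 coarse cells, refinement
#' 10, three countries); the published dataset's scale corresponds to
#' `refinement = 60` and 30 arc-second pixels, which the generator also
#' supports.
#'
#' @param n_coarse_rows,n_coarse_cols coarse lattice dimensions.
#' @param refinement fine pixels per coarse cell side (production scale: 60).
#' @param n_countries number of countries (vertical bands over land).
#' @param clusters_per_country population clusters ("cities") per country.
#' @param baseline_totals numeric vector of country baseline populations;
#'   default draws in `[5e4, 2e5]`.
#' @param growth_rate_range annual country growth-rate range the series
#'   is drawn from (default 1-3 percent, a realistic span for rapidly
#'   growing continental populations).
#' @param urban_share_start,urban_share_increment starting country urban
#'   share and its annual increment (defaults 0.35 and 0.005: about a
#'   third urban, rising half a percentage point per year).
#' @param urban_fraction_peak,urban_fraction_increment peak baseline
#'   coarse-cell urban fraction (most clustered cell) and its annual
#'   increment.
#' @param water_fraction fraction of rows that are water (southern edge).
#' @param years span covered by the scenario series (5-year steps).
#' @param origin_lon,origin_lat,fine_cell_size grid placement; defaults
#'   to 30 arc-second pixels at (10 E, 10 N).
#' @param seed integer RNG seed; identical seeds give identical worlds.
#' @return A `synth_spec`.
#' @export
synth_spec <- function(n_coarse_rows = 2L, n_coarse_cols = 2L,
                       refinement = 10L, n_countries = 3L,
                       clusters_per_country = 2L,
                       baseline_totals = NULL,
                       growth_rate_range = c(0.01, 0.03),
                       urban_share_start = 0.35,
                       urban_share_increment = 0.005,
                       urban_fraction_peak = 0.6,
                       urban_fraction_increment = 0.002,
                       water_fraction = 0.1,
                       years = c(2000L, 2100L),
                       origin_lon = 10, origin_lat = 10,
                       fine_cell_size = 1 / 120,
                       seed = 1L) {
  spec <- list(n_coarse_rows = as.integer(n_coarse_rows),
               n_coarse_cols = as.integer(n_coarse_cols),
               refinement = as.integer(refinement),
               n_countries = as.integer(n_countries),
               clusters_per_country = as.integer(clusters_per_country),
               baseline_totals = baseline_totals,
               growth_rate_range = growth_rate_range,
               urban_share_start = urban_share_start,
               urban_share_increment = urban_share_increment,
               urban_fraction_peak = urban_fraction_peak,
               urban_fraction_increment = urban_fraction_increment,
               water_fraction = water_fraction,
               years = as.integer(range(years)),
               origin_lon = origin_lon, origin_lat = origin_lat,
               fine_cell_size = fine_cell_size,
               seed = as.integer(seed))
  if (spec$n_countries < 1L) stop("need at least one country")
  if (spec$water_fraction < 0 || spec$water_fraction >= 1)
    stop("infeasible water fraction (must lie in [0, 1))")
  if (spec$urban_share_start < 0 || spec$urban_share_start > 1)
    stop("urban_share_start must lie in [0, 1]")
  n_cols <- spec$n_coarse_cols * spec$refinement
  if (n_cols < spec$n_countries)
    stop("more countries than fine columns")
  class(spec) <- "synth_spec"
  spec
}

#' Generate a synthetic toy world
#'
#' Population is a mixture of isotropic clusters (peaked around randomly
#' placed "city" centres) over a low uniform background, scaled per
#' country so each country's grid sum equals its baseline total exactly.
#' Countries are vertical bands tiling the land area (water occupies the
#' southernmost rows); at least one road polyline crosses all countries,
#' and one road per country links its cluster centres.  Baseline urban
#' fractions are proportional to each coarse cell's share of peak
#' population, then trend upward by a fixed annual increment, clipped to
#' `[0, 1]`.  The scenario series runs at five-year steps, starting
#' exactly from the baseline totals; the plausibility matrix is the
#' published SSP-RCP matrix.
#'
#' @param spec a [synth_spec()].
#' @return A list: `geometry`, `baseline` (`fine_grid`), `countries`
#'   (`country_raster`), `country_polygons`, `roads`, `fractions`
#'   (named list of per-year `coarse_grid`, covering `spec$years`),
#'   `series` (`scenario_series` at 5-year steps), `matrix`
#'   (`scenario_matrix`) and `spec`.
#' @export
generate_world <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  R <- spec$refinement
  nr <- spec$n_coarse_rows * R
  nc <- spec$n_coarse_cols * R
  g <- grid_geometry(spec$origin_lon, spec$origin_lat, spec$fine_cell_size,
                     R, nr, nc)

  n_water_rows <- round(spec$water_fraction * nr)
  if (n_water_rows >= nr) stop("infeasible spec: no land rows left")
  land_rows <- nr - n_water_rows

  # vertical country bands over the land area, edges on pixel boundaries
  breaks <- round(seq(0, nc, length.out = spec$n_countries + 1L))
  if (any(diff(breaks) < 1L)) stop("more countries than fine columns")
  cell <- g$fine_cell_size
  lat_top <- g$origin_lat
  lat_bot <- g$origin_lat - land_rows * cell
  polys <- lapply(seq_len(spec$n_countries), function(c) {
    x0 <- g$origin_lon + breaks[c] * cell
    x1 <- g$origin_lon + breaks[c + 1L] * cell
    ring <- rbind(c(x0, lat_bot), c(x1, lat_bot), c(x1, lat_top),
                  c(x0, lat_top), c(x0, lat_bot))
    list(country_id = c, rings = list(ring))
  })
  countries <- rasterize_countries(polys, g)
  land <- countries$valid_mask

  # clustered population: isotropic bumps over a low background
  totals <- spec$baseline_totals
  if (is.null(totals))
    totals <- stats::runif(spec$n_countries, 5e4, 2e5)
  if (length(totals) != spec$n_countries || any(totals < 0))
    stop("baseline_totals must be ", spec$n_countries, " non-negative values")
  ctr <- center_matrices(g)
  pop <- matrix(0, nr, nc)
  cluster_centers <- vector("list", spec$n_countries)
  for (c in seq_len(spec$n_countries)) {
    sel <- which(land & countries$ids == c)
    k <- max(1L, spec$clusters_per_country)
    centers <- sel[sample.int(length(sel), min(k, length(sel)))]
    cluster_centers[[c]] <- cbind(lon = ctr$lon[centers], lat = ctr$lat[centers])
    dens <- rep(0.05, length(sel))              # background
    sigma <- coarse_cell_size(g) / 6
    for (j in seq_len(nrow(cluster_centers[[c]]))) {
      d2 <- (ctr$lon[sel] - cluster_centers[[c]][j, 1L])^2 +
        (ctr$lat[sel] - cluster_centers[[c]][j, 2L])^2
      dens <- dens + stats::runif(1, 0.6, 1.4) * exp(-d2 / (2 * sigma^2))
    }
    if (totals[c] > 0) pop[sel] <- totals[c] * dens / sum(dens)
  }
  baseline <- fine_grid(g, pop, land)

  # roads: one trunk crossing every country plus one per country
  mid_lat <- g$origin_lat - land_rows * cell / 2
  trunk_x <- g$origin_lon + seq(0.5, nc - 0.5, length.out = max(4L, spec$n_coarse_cols + 1L)) * cell
  trunk <- cbind(trunk_x, mid_lat + stats::runif(length(trunk_x), -2, 2) * cell)
  roads <- list(trunk)
  for (c in seq_len(spec$n_countries)) {
    cc <- cluster_centers[[c]]
    if (nrow(cc) >= 2L) roads[[length(roads) + 1L]] <- cc[1:2, , drop = FALSE]
  }

  # urban fractions: baseline proportional to the cell's population share,
  # trending up by a fixed annual increment
  years_all <- seq(spec$years[1L], spec$years[2L])
  cell_pop <- matrix(0, spec$n_coarse_rows, spec$n_coarse_cols)
  cell_has_land <- matrix(FALSE, spec$n_coarse_rows, spec$n_coarse_cols)
  for (cr in seq_len(spec$n_coarse_rows)) for (cc2 in seq_len(spec$n_coarse_cols)) {
    b <- block_of(g, cr, cc2)
    cell_has_land[cr, cc2] <- any(land[b$rows, b$cols])
    cell_pop[cr, cc2] <- sum(pop[b$rows, b$cols][land[b$rows, b$cols]])
  }
  base_frac <- if (max(cell_pop) > 0)
    spec$urban_fraction_peak * cell_pop / max(cell_pop)
  else matrix(0, spec$n_coarse_rows, spec$n_coarse_cols)
  fractions <- lapply(years_all, function(y) {
    f <- base_frac + spec$urban_fraction_increment * (y - years_all[1L])
    f[f < 0] <- 0
    f[f > 1] <- 1
    f[!cell_has_land] <- NA_real_
    coarse_grid(g, f, cell_has_land, check = FALSE)
  })
  names(fractions) <- as.character(years_all)

  # scenario series at five-year steps, anchored exactly at the baseline
  steps <- unique(c(seq(spec$years[1L], spec$years[2L], by = 5L), spec$years[2L]))
  growth <- stats::runif(spec$n_countries, spec$growth_rate_range[1L],
                         spec$growth_rate_range[2L])
  share0 <- pmin(1, pmax(0, spec$urban_share_start +
                           stats::runif(spec$n_countries, -0.05, 0.05)))
  series <- do.call(rbind, lapply(seq_len(spec$n_countries), function(c) {
    data.frame(country_id = c, year = steps,
               total_population = totals[c] * (1 + growth[c])^(steps - steps[1L]),
               urban_share = pmin(1, pmax(0, share0[c] +
                 spec$urban_share_increment * (steps - steps[1L]))))
  }))

  list(geometry = g, baseline = baseline, countries = countries,
       country_polygons = polys, roads = roads, fractions = fractions,
       series = scenario_series(series), matrix = default_scenario_matrix(),
       spec = spec)
}

#' Hand-checkable worked-example world
#'
#' A fixed miniature world (2 x 2 coarse cells, refinement 3, two
#' countries, no randomness) whose population values are small integers,
#' so urban masks and allotments can be verified by hand and by the
#' brute-force subset oracle.  Country 1 occupies the left half, country
#' 2 the right; the bottom row of pixels is water; one road runs
#' horizontally through the middle.
#'
#' @return A list shaped like [generate_world()]'s value.
#' @export
worked_example_world <- function() {
  g <- grid_geometry(0, 0, 1, refinement = 3L, n_fine_rows = 6L, n_fine_cols = 6L)
  pop <- matrix(c(
    9, 7, 1, 2, 8, 1,
    6, 5, 2, 1, 4, 2,
    1, 2, 3, 3, 2, 1,
    4, 1, 2, 5, 6, 2,
    2, 3, 1, 2, 3, 4,
    0, 0, 0, 0, 0, 0), 6, 6, byrow = TRUE)
  land <- matrix(TRUE, 6, 6)
  land[6, ] <- FALSE                     # water row
  ids <- matrix(rep(c(1L, 1L, 1L, 2L, 2L, 2L), each = 6), 6, 6, byrow = TRUE)
  ids[!land] <- NA_integer_
  countries <- country_raster(g, ids)
  pop[!land] <- NA_real_
  baseline <- fine_grid(g, pop, land)
  roads <- list(cbind(c(0, 6), c(-2.5, -2.5)))
  years <- 2000:2010
  f <- matrix(0.5, 2, 2)
  fractions <- lapply(years, function(y) coarse_grid(g, f))
  names(fractions) <- as.character(years)
  steps <- c(2000L, 2005L, 2010L)
  t1 <- sum(pop[land & ids == 1L])
  t2 <- sum(pop[land & ids == 2L])
  series <- scenario_series(data.frame(
    country_id = rep(c(1L, 2L), each = 3L),
    year = rep(steps, 2L),
    total_population = c(t1 * c(1, 1.1, 1.2), t2 * c(1, 1.15, 1.3)),
    urban_share = rep(c(0.4, 0.45, 0.5), 2L)))
  list(geometry = g, baseline = baseline, countries = countries,
       country_polygons = list(
         list(country_id = 1L, rings = list(rbind(c(0, -5), c(3, -5), c(3, 0),
                                                  c(0, 0), c(0, -5)))),
         list(country_id = 2L, rings = list(rbind(c(3, -5), c(6, -5), c(6, 0),
                                                  c(3, 0), c(3, -5))))),
       roads = roads, fractions = fractions, series = series,
       matrix = default_scenario_matrix())
}
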