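#' Build the baseline unique-population surface
#'
#' Convenience wrapper for the baseline-year preparation: Euclidean
#' distance to roads and to per-coarse-cell population centres of
#' gravity, each inverted and rescaled into `[lo, hi]`, then added to
#' the baseline population to make every pixel's value unique for
#' ranking.
#'
#' @param pop baseline population `fine_grid` (valid mask = land).
#' @param roads list of road polyline matrices.
#' @param lo,hi perturbation bounds (published values `1.0e-5`,
#'   `1.1e-5`).
#' @return A `unique_population`.
#' @export
baseline_unique_population <- function(pop, roads, lo = 1.0e-5, hi = 1.1e-5) {
  g <- pop$geometry
  d_road <- distance_to_roads(roads, g, valid_mask = pop$valid_mask)
  cogs <- compute_cogs(pop)
  d_cog <- distance_to_cog(cogs, g, valid_mask = pop$valid_mask)
  make_unique_population(pop,
                         inverse_rescale(d_road, lo, hi),
                         inverse_rescale(d_cog, lo, hi))
}

#' Run configuration
#'
#' Plain-text (YAML key-value) run configuration; every method constant
#' surfaces as a key with the published value as default.  Paths are
#' resolved relative to the config file's directory.
#'
#' Keys: `baseline` (GeoTIFF), `countries`, `roads` (GeoJSON),
#' `urban_fraction_pattern` (GeoTIFF path with `{rcp}` and `{year}`
#' placeholders), `series_pattern` (CSV path with `{ssp}`), `matrix`
#' (CSV; defaults to the packaged matrix), `out_dir`, `refinement`
#' (default 60), `years` (two-element range, default 2000-2100),
#' `scenarios` (`"all"` for every positive-probability combination, or
#' a list like `"1-4.5"`), `perturb_lo`/`perturb_hi` (defaults `1.0e-5`
#' / `1.1e-5`), `nodata` (default -9999), `seed` (synthetic module
#' only).
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base_dir <- dirname(normalizePath(path))
  defaults <- list(refinement = 60L, years = c(2000L, 2100L),
                   scenarios = "all", perturb_lo = 1.0e-5,
                   perturb_hi = 1.1e-5, nodata = -9999, seed = 1L,
                   matrix = NULL)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  need <- c("baseline", "countries", "roads", "urban_fraction_pattern",
            "series_pattern", "out_dir")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("run config missing key(s): ", paste(miss, collapse = ", "))
  rel <- function(p) {
    if (is.null(p) || grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  }
  for (k in c("baseline", "countries", "roads", "urban_fraction_pattern",
              "series_pattern", "matrix", "out_dir"))
    cfg[[k]] <- rel(cfg[[k]])
  cfg$years <- as.integer(range(unlist(cfg$years)))
  cfg$refinement <- as.integer(cfg$refinement)
  class(cfg) <- "run_config"
  cfg
}

fill_pattern <- function(pattern, ssp = NULL, rcp = NULL, year = NULL) {
  if (!is.null(ssp)) pattern <- gsub("{ssp}", ssp, pattern, fixed = TRUE)
  if (!is.null(rcp)) pattern <- gsub("{rcp}", format(rcp, nsmall = 1), pattern, fixed = TRUE)
  if (!is.null(year)) pattern <- gsub("{year}", year, pattern, fixed = TRUE)
  pattern
}

parse_scenario_labels <- function(x) {
  # labels like "1-4.5" or "2-8.5"
  parts <- strsplit(x, "-", fixed = TRUE)
  data.frame(ssp = as.integer(vapply(parts, `[[`, "", 1L)),
             rcp = as.numeric(vapply(parts, `[[`, "", 2L)))
}

#' Run the projection described by a config
#'
#' Loads every input, builds the baseline unique-population surface,
#' iterates the annual loop for each selected SSP-RCP combination, and
#' writes one GeoTIFF per scenario and year named
#' `ssp<ssp>_rcp<rcp>_<year>.tif` into `out_dir`.  Per-year progress
#' lines report the per-country conservation residual.
#'
#' @param config a [read_run_config()] result (or path to a config file).
#' @param verbose print progress lines.
#' @return Invisibly, a named list of `population_projection` objects,
#'   one per scenario combination.
#' @export
run_projection <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  years <- seq(config$years[1L], config$years[2L])

  baseline0 <- read_raster(config$baseline, refinement = config$refinement)
  geometry <- baseline0$geometry
  polys <- read_countries_geojson(config$countries)
  countries <- rasterize_countries(polys, geometry)
  land <- countries$valid_mask & baseline0$valid_mask
  baseline <- fine_grid(geometry, baseline0$values, land, check = FALSE)
  roads <- read_roads_geojson(config$roads)
  unique_pop <- baseline_unique_population(baseline, roads,
                                           config$perturb_lo, config$perturb_hi)

  mat <- if (is.null(config$matrix)) default_scenario_matrix()
         else read_matrix_csv(config$matrix)
  combos <- select_scenarios(mat)
  if (!identical(config$scenarios, "all")) {
    want <- parse_scenario_labels(unlist(config$scenarios))
    keep <- paste(combos$ssp, combos$rcp) %in% paste(want$ssp, want$rcp)
    combos <- combos[keep, , drop = FALSE]
  }
  if (nrow(combos) == 0L) stop("no scenario combinations selected")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  runs <- list()
  for (i in seq_len(nrow(combos))) {
    ssp <- combos$ssp[i]; rcp <- combos$rcp[i]
    label <- sprintf("ssp%d_rcp%s", ssp, format(rcp, nsmall = 1))
    if (verbose) message("scenario ", label)
    series <- annualize(read_scenario_csv(fill_pattern(config$series_pattern,
                                                       ssp = ssp)),
                        years = years)
    fractions <- lapply(years, function(y)
      read_raster(fill_pattern(config$urban_fraction_pattern, rcp = rcp, year = y),
                  geometry = geometry, role = "coarse"))
    names(fractions) <- as.character(years)
    run <- project_scenario(unique_pop, fractions, countries, series, years,
                            verbose = verbose)
    for (y in years)
      write_raster(run$grids[[as.character(y)]],
                   file.path(config$out_dir,
                             sprintf("%s_%d.tif", label, y)),
                   nodata = config$nodata)
    runs[[label]] <- run
  }
  invisible(runs)
}

#' Write a synthetic world to disk in the run input formats
#'
#' Serialises a [generate_world()] result exactly as [run_projection()]
#' expects it: `baseline.tif`, `countries.geojson`, `roads.geojson`,
#' per-year urban-fraction GeoTIFFs (one set per requested RCP label;
#' synthetic fractions do not differentiate RCPs), one scenario CSV per
#' requested SSP (synthetic series do not differentiate SSP narratives),
#' the probability-matrix CSV, and a ready-to-run `config.yaml`.
#'
#' @param world a [generate_world()] result.
#' @param dir output directory (created if needed).
#' @param ssps,rcps scenario labels to materialise files for.
#' @param years year range to cover (default: the world's series span).
#' @return The path of the written config file, invisibly.
#' @export
write_world <- function(world, dir, ssps = 1L, rcps = 4.5, years = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(years))
    years <- range(as.integer(names(world$fractions)))
  yrs <- seq(years[1L], years[2L])
  write_raster(world$baseline, file.path(dir, "baseline.tif"))
  write_countries_geojson(world$country_polygons,
                          file.path(dir, "countries.geojson"))
  write_roads_geojson(world$roads, file.path(dir, "roads.geojson"))
  for (r in rcps) for (y in yrs)
    write_raster(world$fractions[[as.character(y)]],
                 file.path(dir, sprintf("urban_rcp%s_%d.tif",
                                        format(r, nsmall = 1), y)))
  for (s in ssps)
    write_scenario_csv(world$series,
                       file.path(dir, sprintf("series_ssp%d.csv", s)))
  write_matrix_csv(world$matrix, file.path(dir, "ssp_rcp_matrix.csv"))
  cfg <- list(baseline = "baseline.tif",
              countries = "countries.geojson",
              roads = "roads.geojson",
              urban_fraction_pattern = "urban_rcp{rcp}_{year}.tif",
              series_pattern = "series_ssp{ssp}.csv",
              matrix = "ssp_rcp_matrix.csv",
              out_dir = "output",
              refinement = world$geometry$refinement,
              years = as.integer(c(years[1L], years[2L])),
              scenarios = sprintf("%d-%s", rep(ssps, each = length(rcps)),
                                  format(rcps, nsmall = 1)),
              seed = world$spec$seed %||% 1L)
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
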