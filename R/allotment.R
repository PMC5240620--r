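#' Mass-conserving proportional population allotment
#'
#' Distributes one year of country-level scenario population over the
#' fine grid.  Within each country the urban mask splits the valid pixels
#' into an urban and a rural stratum; the country's urban population
#' (`urban_share * total`) is shared over the urban stratum
#' proportionally to the previous grid values (the "weights"), and the
#' rural remainder likewise over the rural stratum.  Proportional sharing
#' preserves pairwise pixel ratios within a stratum: a pixel that starts
#' with twice another's value keeps twice its value whenever both lie in
#' the same country and stratum.  A stratum whose weights sum to zero but
#' whose target is positive receives the target spread uniformly, so mass
#' is conserved in every case.
#'
#' @param prev_pop `fine_grid` of weights: the unique population in the
#'   baseline year, the previous year's output thereafter.
#' @param mask an [build_urban_mask()] result sharing the geometry.
#' @param countries a [country_raster()].
#' @param series an annualized [scenario_series()].
#' @param year the year whose series entries to use.
#' @return A `fine_grid` of people per pixel; for every country the pixel
#'   sum equals the series total to accumulation tolerance.
#' @export
allot_population <- function(prev_pop, mask, countries, series, year) {
  stopifnot(inherits(prev_pop, "fine_grid"), inherits(mask, "urban_mask"),
            inherits(countries, "country_raster"),
            inherits(series, "scenario_series"))
  stop_if_geometry_differs(prev_pop$geometry, mask$geometry, "pop and mask")
  stop_if_geometry_differs(prev_pop$geometry, countries$geometry,
                           "pop and countries")
  yr <- series[series$year == year, , drop = FALSE]
  ids <- country_ids(countries)
  missing_ids <- setdiff(ids, yr$country_id)
  if (length(missing_ids))
    stop("no scenario entry for year ", year, " for country id(s): ",
         paste(missing_ids, collapse = ", "))
  extra <- setdiff(yr$country_id, ids)
  if (length(extra))
    warning("scenario series has countries absent from the raster ",
            "(ignored): ", paste(extra, collapse = ", "))
  if (any(yr$total_population < 0))
    stop("negative total_population in scenario series")

  vm <- prev_pop$valid_mask & countries$valid_mask
  out <- matrix(NA_real_, nrow(prev_pop$values), ncol(prev_pop$values))
  out[vm] <- 0
  for (cid in ids) {
    row <- yr[yr$country_id == cid, ]
    target_urban <- row$total_population * row$urban_share
    target_rural <- row$total_population - target_urban
    in_country <- vm & countries$ids == cid
    in_country[is.na(in_country)] <- FALSE
    if (sum(in_country) == 0L) {
      if (row$total_population > 0)
        stop("country ", cid, " has no valid pixels under the combined ",
             "mask but a positive population target: mass would be lost")
      next
    }
    sel_urban <- in_country & mask$urban
    sel_rural <- in_country & !mask$urban
    # a country may have no urban pixels (all its cells round to k = 0)
    # or no rural ones (fraction 1 everywhere); mass must still balance,
    # so an empty stratum's target moves to the other stratum.
    if (sum(sel_urban) == 0L && target_urban > 0) {
      warning("country ", cid, ", year ", year, ": urban target ",
              "reassigned to rural stratum (no urban pixels)")
      target_rural <- target_rural + target_urban
      target_urban <- 0
    }
    if (sum(sel_rural) == 0L && target_rural > 0) {
      warning("country ", cid, ", year ", year, ": rural target ",
              "reassigned to urban stratum (no rural pixels)")
      target_urban <- target_urban + target_rural
      target_rural <- 0
    }
    for (stratum in c("urban", "rural")) {
      sel <- if (stratum == "urban") sel_urban else sel_rural
      target <- if (stratum == "urban") target_urban else target_rural
      n <- sum(sel)
      if (n == 0L) next
      w <- prev_pop$values[sel]
      s <- sum(w)
      out[sel] <- if (s > 0) target * w / s else target / n
    }
  }
  fine_grid(prev_pop$geometry, out, vm)
}

#' Project a scenario through the annual downscaling loop
#'
#' Runs the full annual loop for one SSP-RCP combination: in the first
#' year the unique-population surface both ranks the pixels (urban mask
#' from the year's urban-fraction grid) and serves as allotment weights,
#' so even the first output is a scenario-consistent redistribution; in
#' every later year the previous year's output grid takes over both
#' roles, the tie-break by pixel index keeping the ranking strict.  The
#' perturbation layers are added once, at baseline, only.
#'
#' @param baseline_unique a [make_unique_population()] surface (or any
#'   `fine_grid` of ranking weights for the first year).
#' @param urban_fractions named list of `coarse_grid`s, one per year
#'   (names are years, e.g. `"2000"`).
#' @param countries a [country_raster()].
#' @param series an annualized [scenario_series()] covering all years and
#'   all raster countries.
#' @param years integer vector of consecutive years to produce.
#' @param verbose print per-year conservation residuals.
#' @return A `population_projection`: list with `years`, `grids` (one
#'   `fine_grid` per year), `masks` summary (`urban_pixels` per year) and
#'   `conservation` (per year, max relative country residual).
#' @export
project_scenario <- function(baseline_unique, urban_fractions, countries,
                             series, years, verbose = FALSE) {
  stopifnot(inherits(baseline_unique, "fine_grid"),
            inherits(countries, "country_raster"),
            inherits(series, "scenario_series"))
  years <- as.integer(years)
  if (length(years) < 1L || any(diff(years) != 1L))
    stop("`years` must be a consecutive ascending run of years")
  have_frac <- as.character(years) %in% names(urban_fractions)
  if (!all(have_frac))
    stop("missing urban-fraction grid for year(s): ",
         paste(years[!have_frac], collapse = ", "))
  ids <- country_ids(countries)
  for (y in years) {
    present <- ids %in% series$country_id[series$year == y]
    if (!all(present))
      stop("scenario series misses year ", y, " for country id(s): ",
           paste(ids[!present], collapse = ", "))
  }

  grids <- vector("list", length(years))
  names(grids) <- as.character(years)
  urban_px <- integer(length(years))
  resid <- numeric(length(years))
  weights <- baseline_unique
  for (i in seq_along(years)) {
    y <- years[i]
    mask <- build_urban_mask(weights, urban_fractions[[as.character(y)]])
    out <- allot_population(weights, mask, countries, series, y)
    grids[[i]] <- out
    urban_px[i] <- sum(mask$urban & mask$valid_mask)
    resid[i] <- max_conservation_residual(out, countries, series, y)
    if (verbose)
      message(sprintf("year %d: %d urban pixels, max country residual %.3g",
                      y, urban_px[i], resid[i]))
    weights <- out
  }
  structure(list(years = years, grids = grids, urban_pixels = urban_px,
                 conservation = resid, countries = ids),
            class = "population_projection")
}

max_conservation_residual <- function(grid, countries, series, year) {
  agg <- aggregate_by_region(grid, countries)
  yr <- series[series$year == year, ]
  ref <- yr$total_population[match(agg$region_id, yr$country_id)]
  rel <- abs(agg$population - ref) / pmax(ref, 1)
  max(rel)
}

#' @export
print.population_projection <- function(x, ...) {
  cat(sprintf("<population_projection> %d years (%d-%d), %d countries\n",
              length(x$years), min(x$years), max(x$years), length(x$countries)))
  cat(sprintf("  max country conservation residual over run: %.3g\n",
              max(x$conservation)))
  invisible(x)
}

#' @export
summary.population_projection <- function(object, ...) {
  totals <- vapply(object$grids,
                   function(g) sum(g$values[g$valid_mask]), numeric(1))
  out <- data.frame(year = object$years,
                    total_population = as.numeric(totals),
                    urban_pixels = object$urban_pixels,
                    max_rel_residual = object$conservation)
  rownames(out) <- NULL
  class(out) <- c("summary.population_projection", "data.frame")
  out
}

#' @export
print.summary.population_projection <- function(x, ...) {
  cat("Projection summary (one row per year):\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' @export
plot.population_projection <- function(x, which = c("totals", "map"),
                                       year = max(x$years), ...) {
  which <- match.arg(which)
  if (which == "totals") {
    s <- summary(x)
    graphics::plot(s$year, s$total_population, type = "b", pch = 16,
                   xlab = "year", ylab = "total population",
                   main = "Projected total population", ...)
  } else {
    plot(x$grids[[as.character(year)]], main = paste("population", year), ...)
  }
  invisible(x)
}
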