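#' Aggregate a population grid to regions
#'
#' Zonal sum: for every region id on the raster, the total of the grid's
#' valid pixel values.  Aggregation is mass-preserving: the region totals
#' sum to the grid total over pixels that carry a region id.
#'
#' @param pop a `fine_grid`.
#' @param regions a [country_raster()] of region (country or admin) ids.
#' @param ids optional id vector to report; ids absent from the raster
#'   are reported with `n_pixels = 0`, `population = 0` and flagged.
#' @return Data frame: `region_id`, `n_pixels`, `population`, `empty`.
#' @export
aggregate_by_region <- function(pop, regions, ids = NULL) {
  stopifnot(inherits(pop, "fine_grid"), inherits(regions, "country_raster"))
  stop_if_geometry_differs(pop$geometry, regions$geometry,
                           "population and region grids")
  sel <- pop$valid_mask & regions$valid_mask
  vals <- pop$values[sel]
  rid <- regions$ids[sel]
  sums <- tapply(vals, rid, sum)
  counts <- tapply(vals, rid, length)
  present <- as.integer(names(sums))
  if (is.null(ids)) ids <- present
  m <- match(ids, present)
  out <- data.frame(
    region_id = as.integer(ids),
    n_pixels = ifelse(is.na(m), 0L, as.integer(counts[m])),
    population = ifelse(is.na(m), 0, as.numeric(sums[m])),
    empty = is.na(m)
  )
  out[order(out$region_id), , drop = FALSE]
}

#' Compare aggregated totals against a reference
#'
#' One-to-one validation of region totals: the coefficient of
#' determination is computed about the identity line, `r2 = 1 -
#' SS_res / SS_tot` with residuals `aggregated - reference` and `SS_tot`
#' the reference's sum of squares about its mean, together with the root
#' mean square error.  A perfectly conserving pipeline, aggregated back
#' to the countries that drove it, gives `r2 = 1` and `RMSE = 0`.  The
#' regression-based variant (residuals about an ordinary least-squares
#' fit) is available for comparisons against independent products, where
#' totals are not expected to match one-to-one.
#'
#' @param aggregated data frame with `region_id` and `population`
#'   (e.g. from [aggregate_by_region()]).
#' @param reference data frame with `region_id` and `population`; the
#'   region id sets must coincide.
#' @param method `"one_to_one"` (default) or `"regression"`.
#' @return A `validation_report`: list with the per-region table
#'   (`regions`), `n`, `r2` (`NA` with a `note` when undefined) and
#'   `rmse`.
#' @export
region_compare <- function(aggregated, reference,
                           method = c("one_to_one", "regression")) {
  method <- match.arg(method)
  stopifnot(all(c("region_id", "population") %in% names(aggregated)),
            all(c("region_id", "population") %in% names(reference)))
  if (!setequal(aggregated$region_id, reference$region_id))
    stop("aggregated and reference cover different region id sets")
  ord <- order(aggregated$region_id)
  agg <- aggregated[ord, , drop = FALSE]
  ref <- reference[match(agg$region_id, reference$region_id), , drop = FALSE]
  tab <- data.frame(region_id = agg$region_id,
                    n_pixels = if ("n_pixels" %in% names(agg)) agg$n_pixels else NA_integer_,
                    population = agg$population,
                    reference = ref$population)
  rownames(tab) <- NULL
  n <- nrow(tab)
  rmse <- sqrt(mean((tab$population - tab$reference)^2))
  r2 <- NA_real_
  note <- NULL
  if (n < 2L) {
    note <- "fewer than 2 regions: r2 undefined"
  } else {
    ss_tot <- sum((tab$reference - mean(tab$reference))^2)
    if (method == "one_to_one") {
      if (ss_tot == 0) {
        if (all(tab$population == tab$reference)) r2 <- 1
        else note <- "reference values all equal: r2 undefined"
      } else {
        r2 <- 1 - sum((tab$population - tab$reference)^2) / ss_tot
      }
    } else {
      if (stats::var(tab$population) == 0 || ss_tot == 0)
        note <- "degenerate variance: regression r2 undefined"
      else
        r2 <- stats::cor(tab$population, tab$reference)^2
    }
  }
  structure(list(regions = tab, n = n, r2 = r2, rmse = rmse,
                 method = method, note = note),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d regions (%s)\n", x$n, x$method))
  cat(sprintf("  r2   = %s\n",
              if (is.na(x$r2)) paste0("NA (", x$note, ")")
              else format(x$r2, digits = 8)))
  cat(sprintf("  RMSE = %g persons\n", x$rmse))
  invisible(x)
}

#' @export
plot.validation_report <- function(x, ...) {
  graphics::plot(x$regions$reference, x$regions$population,
                 xlab = "reference population", ylab = "aggregated population",
                 main = sprintf("One-to-one validation (r2 = %s)",
                                format(x$r2, digits = 4)), pch = 16, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Per-region population change comparison
#'
#' Pairs the aggregated change between two grids (`t1 - t0` per region)
#' with the corresponding reference change, ready for a one-to-one
#' change scatter (the style used to compare five-year changes against
#' an independent gridded product at admin level 2).
#'
#' @param pop_t0,pop_t1 `fine_grid`s sharing geometry.
#' @param regions a [country_raster()].
#' @param ref_t0,ref_t1 data frames with `region_id`, `population`.
#' @return Data frame: `region_id`, `change`, `reference_change`.
#' @export
change_report <- function(pop_t0, pop_t1, regions, ref_t0, ref_t1) {
  a0 <- aggregate_by_region(pop_t0, regions)
  a1 <- aggregate_by_region(pop_t1, regions)
  if (!setequal(ref_t0$region_id, a0$region_id) ||
      !setequal(ref_t1$region_id, a0$region_id))
    stop("reference tables cover different region id sets than the raster")
  m0 <- match(a0$region_id, ref_t0$region_id)
  m1 <- match(a0$region_id, ref_t1$region_id)
  data.frame(region_id = a0$region_id,
             change = a1$population - a0$population,
             reference_change = ref_t1$population[m1] - ref_t0$population[m0])
}
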