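#' Rescaled inverse-distance perturbation layer
#'
#' Converts a distance layer into the tiny additive perturbation used to
#' make pixel populations unique: first the bounded inverse `v = 1 / (d +
#' delta)` with `delta` equal to one fine cell size (so the inverse stays
#' finite on pixels crossed by a road), then a single affine map over the
#' whole domain taking the smallest `v` to `lo` and the largest to `hi`.
#' Because the affine map is increasing, the perturbation strictly
#' reverses the distance order: the pixel nearest a feature receives the
#' largest perturbation `hi`, the farthest receives `lo`.  The published
#' bounds are `lo = 1.0e-5`, `hi = 1.1e-5` people.
#'
#' @param dist a `fine_grid` of non-negative distances (degrees).
#' @param lo,hi target bounds, `0 < lo < hi`.
#' @param delta inverse-distance offset in degrees; defaults to the fine
#'   cell size.
#' @return A `fine_grid` with valid values in `[lo, hi]`.
#' @export
inverse_rescale <- function(dist, lo = 1.0e-5, hi = 1.1e-5, delta = NULL) {
  stopifnot(inherits(dist, "fine_grid"), lo > 0, hi > lo)
  if (is.null(delta)) delta <- dist$geometry$fine_cell_size
  d <- dist$values[dist$valid_mask]
  if (length(d) < 2L) stop("need at least 2 valid distance values")
  if (any(d < 0)) stop("distances must be non-negative")
  v <- 1 / (d + delta)
  vmin <- min(v); vmax <- max(v)
  if (vmax == vmin)
    stop("all valid distances are identical: rescaled ordering undefined")
  out <- matrix(NA_real_, nrow(dist$values), ncol(dist$values))
  out[dist$valid_mask] <- lo + (v - vmin) * (hi - lo) / (vmax - vmin)
  fine_grid(dist$geometry, out, dist$valid_mask)
}

#' Tie-free "unique population" surface
#'
#' Adds the two rescaled inverse-distance layers (roads, centres of
#' gravity) to the baseline population so that pixels within each coarse
#' cell can be ranked without ties.  The perturbation total is bounded by
#' `max(inv_road) + max(inv_cog)` (2.2e-5 with the default bounds), so
#' any two pixels whose raw populations differ by more than that bound
#' keep their raw order.  Residual exact ties (possible only between
#' pixels with identical population *and* identical perturbations) are
#' broken deterministically by linear pixel index (R's native
#' column-major order), giving a strict total order within every coarse
#' cell.
#'
#' @param pop baseline population `fine_grid` (people per pixel, >= 0).
#' @param inv_road,inv_cog perturbation layers from [inverse_rescale()],
#'   sharing `pop`'s geometry and valid mask.
#' @return A `unique_population` object (a `fine_grid` subclass whose
#'   ranking convention is value descending, then linear pixel index
#'   ascending).
#' @export
make_unique_population <- function(pop, inv_road, inv_cog) {
  stopifnot(inherits(pop, "fine_grid"), inherits(inv_road, "fine_grid"),
            inherits(inv_cog, "fine_grid"))
  stop_if_geometry_differs(pop$geometry, inv_road$geometry, "pop and inv_road")
  stop_if_geometry_differs(pop$geometry, inv_cog$geometry, "pop and inv_cog")
  if (!identical(pop$valid_mask, inv_road$valid_mask) ||
      !identical(pop$valid_mask, inv_cog$valid_mask))
    stop("the three layers must share one valid mask")
  if (any(pop$values[pop$valid_mask] < 0))
    stop("population values must be non-negative")
  vals <- pop$values + inv_road$values + inv_cog$values
  vals[!pop$valid_mask] <- NA_real_
  out <- fine_grid(pop$geometry, vals, pop$valid_mask)
  perturbation_bound <- max(inv_road$values[pop$valid_mask]) +
    max(inv_cog$values[pop$valid_mask])
  structure(c(unclass(out), list(perturbation_bound = perturbation_bound)),
            class = c("unique_population", "fine_grid"))
}

# ranking convention shared by mask building everywhere: value descending,
# exact ties by ascending linear (column-major) index.  order() with radix
# is stable, so sorting descending preserves index order among ties.
rank_order <- function(values, linear_index) {
  ord <- order(values, decreasing = TRUE, method = "radix")
  linear_index[ord]
}

#' Urban mask by per-cell top-k selection
#'
#' Implements the core classification step: within each coarse cell the
#' fine pixels are sorted by their (unique) population value and the
#' highest ones selected as urban until the cell's urban fraction is
#' fulfilled.  The target count is `k = round(fraction * R^2)` with halves
#' rounded away from zero ("nearest integer"), computed from the full cell
#' area and then capped at the number of valid land pixels so water is
#' never urbanised.
#'
#' @param unique_pop a `fine_grid` (normally a `unique_population` in the
#'   baseline year, or the previous year's population grid thereafter).
#' @param urban_fraction a `coarse_grid` with values in `[0, 1]` on valid
#'   cells; invalid coarse cells yield no urban pixels.
#' @return An `urban_mask` object: a `fine_grid` whose values are 0/1,
#'   with `urban` (logical matrix) attached.
#' @export
build_urban_mask <- function(unique_pop, urban_fraction) {
  stopifnot(inherits(unique_pop, "fine_grid"), inherits(urban_fraction, "coarse_grid"))
  stop_if_geometry_differs(unique_pop$geometry, urban_fraction$geometry,
                           "population and urban-fraction grids")
  g <- unique_pop$geometry
  R <- g$refinement
  frac <- urban_fraction$values
  fvalid <- urban_fraction$valid_mask
  if (any(frac[fvalid] < 0 | frac[fvalid] > 1))
    stop("urban fractions must lie in [0, 1] on valid cells")
  urban <- matrix(FALSE, g$n_fine_rows, g$n_fine_cols)
  vm <- unique_pop$valid_mask
  vals <- unique_pop$values
  for (cr in seq_len(n_coarse_rows(g))) {
    for (cc in seq_len(n_coarse_cols(g))) {
      if (!fvalid[cr, cc]) next
      b <- block_of(g, cr, cc)
      sub_valid <- vm[b$rows, b$cols]
      n_valid <- sum(sub_valid)
      if (n_valid == 0L) next
      k <- round_half_away(frac[cr, cc] * R * R)
      k <- min(as.integer(k), n_valid)
      if (k == 0L) next
      sub_vals <- vals[b$rows, b$cols]
      lin <- which(sub_valid)                    # column-major within block
      ord <- rank_order(sub_vals[lin], lin)
      sel <- matrix(FALSE, R, R)
      sel[ord[seq_len(k)]] <- TRUE
      urban[b$rows, b$cols] <- sel
    }
  }
  out <- fine_grid(g, matrix(as.numeric(urban), nrow(urban), ncol(urban)), vm,
                   check = FALSE)
  structure(c(unclass(out), list(urban = urban)),
            class = c("urban_mask", "fine_grid"))
}

#' @export
print.urban_mask <- function(x, ...) {
  cat(sprintf("<urban_mask> %d x %d: %d urban of %d valid pixels\n",
              nrow(x$urban), ncol(x$urban), sum(x$urban & x$valid_mask),
              sum(x$valid_mask)))
  invisible(x)
}

#' Per-coarse-cell urban pixel counts
#' @param mask an `urban_mask`.
#' @return Integer matrix on the coarse lattice.
#' @export
urban_counts <- function(mask) {
  stopifnot(inherits(mask, "urban_mask"))
  g <- mask$geometry
  out <- matrix(0L, n_coarse_rows(g), n_coarse_cols(g))
  for (cr in seq_len(nrow(out))) for (cc in seq_len(ncol(out))) {
    b <- block_of(g, cr, cc)
    out[cr, cc] <- sum(mask$urban[b$rows, b$cols])
  }
  out
}
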