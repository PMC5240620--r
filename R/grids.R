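#' Georeferenced grid containers
#'
#' Three light S3 containers share a [grid_geometry()]:
#' * `fine_grid` — real values on the fine lattice (population counts,
#'   distances, perturbations) plus a logical validity mask.  Invalid
#'   pixels (water or outside the domain) are never read by any algorithm
#'   and are serialised as the nodata sentinel.
#' * `coarse_grid` — values on the coarse lattice, one per `R x R` block
#'   of fine pixels; used for urban fractions, which must lie in `[0, 1]`
#'   on valid cells.
#' * `country_raster` — positive integer country identifiers on the fine
#'   lattice; every valid pixel carries exactly one id.
#'
#' @param geometry a [grid_geometry()].
#' @param values numeric matrix, `n_fine_rows x n_fine_cols` for fine grids
#'   and `n_coarse_rows x n_coarse_cols` for coarse grids.
#' @param valid_mask logical matrix of the same shape; `FALSE` marks
#'   water/outside pixels.  Defaults to everything valid (fine/coarse) or
#'   to `!is.na(ids)` (country rasters).
#' @param check validate value invariants (non-negative population etc.);
#'   set `FALSE` only for internal intermediates.
#' @return An object of class `fine_grid`, `coarse_grid` or
#'   `country_raster`.
#' @name grids
NULL

#' @rdname grids
#' @export
fine_grid <- function(geometry, values, valid_mask = NULL, check = TRUE) {
  stopifnot(inherits(geometry, "grid_geometry"), is.matrix(values))
  if (!all(dim(values) == c(geometry$n_fine_rows, geometry$n_fine_cols)))
    stop("`values` must be ", geometry$n_fine_rows, " x ", geometry$n_fine_cols)
  if (is.null(valid_mask))
    valid_mask <- matrix(TRUE, nrow(values), ncol(values))
  stopifnot(is.logical(valid_mask), all(dim(valid_mask) == dim(values)))
  valid_mask[is.na(valid_mask)] <- FALSE
  if (check && any(!is.finite(values[valid_mask])))
    stop("fine_grid has non-finite values on valid pixels")
  storage.mode(values) <- "double"
  structure(list(geometry = geometry, values = values, valid_mask = valid_mask),
            class = "fine_grid")
}

#' @rdname grids
#' @export
coarse_grid <- function(geometry, values, valid_mask = NULL, check = TRUE) {
  stopifnot(inherits(geometry, "grid_geometry"), is.matrix(values))
  nr <- n_coarse_rows(geometry); nc <- n_coarse_cols(geometry)
  if (!all(dim(values) == c(nr, nc)))
    stop("`values` must be ", nr, " x ", nc, " (coarse lattice)")
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, nr, nc)
  stopifnot(is.logical(valid_mask), all(dim(valid_mask) == dim(values)))
  valid_mask[is.na(valid_mask)] <- FALSE
  if (check && any(!is.finite(values[valid_mask])))
    stop("coarse_grid has non-finite values on valid cells")
  storage.mode(values) <- "double"
  structure(list(geometry = geometry, values = values, valid_mask = valid_mask),
            class = "coarse_grid")
}

#' @rdname grids
#' @param ids integer matrix of country identifiers (> 0) on the fine
#'   lattice; `NA` where no country.
#' @export
country_raster <- function(geometry, ids, valid_mask = NULL) {
  stopifnot(inherits(geometry, "grid_geometry"), is.matrix(ids))
  if (!all(dim(ids) == c(geometry$n_fine_rows, geometry$n_fine_cols)))
    stop("`ids` must be ", geometry$n_fine_rows, " x ", geometry$n_fine_cols)
  storage.mode(ids) <- "integer"
  if (is.null(valid_mask)) valid_mask <- !is.na(ids)
  stopifnot(is.logical(valid_mask), all(dim(valid_mask) == dim(ids)))
  valid_mask[is.na(valid_mask)] <- FALSE
  valid_mask[is.na(ids)] <- FALSE
  if (any(ids[valid_mask] < 1L))
    stop("country ids must be positive integers on valid pixels")
  structure(list(geometry = geometry, ids = ids, valid_mask = valid_mask),
            class = "country_raster")
}

#' @export
print.fine_grid <- function(x, ...) {
  v <- x$values[x$valid_mask]
  cat(sprintf("<fine_grid> %d x %d (%d valid); range [%g, %g], sum %g\n",
              nrow(x$values), ncol(x$values), sum(x$valid_mask),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              if (length(v)) sum(v) else 0))
  invisible(x)
}

#' @export
print.coarse_grid <- function(x, ...) {
  v <- x$values[x$valid_mask]
  cat(sprintf("<coarse_grid> %d x %d (%d valid); range [%g, %g]\n",
              nrow(x$values), ncol(x$values), sum(x$valid_mask),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' @export
print.country_raster <- function(x, ...) {
  ids <- sort(unique(x$ids[x$valid_mask]))
  cat(sprintf("<country_raster> %d x %d (%d valid); %d countries: %s\n",
              nrow(x$ids), ncol(x$ids), sum(x$valid_mask), length(ids),
              paste(utils::head(ids, 10L), collapse = ", ")))
  invisible(x)
}

#' @export
plot.fine_grid <- function(x, main = "", ...) {
  z <- x$values
  z[!x$valid_mask] <- NA
  # image() draws row 1 at the bottom; flip so north stays up
  graphics::image(t(z[nrow(z):1, , drop = FALSE]), axes = FALSE, main = main,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Country identifiers present on a raster
#' @param countries a [country_raster()].
#' @return Sorted integer vector of ids occurring on valid pixels.
#' @export
country_ids <- function(countries) {
  stopifnot(inherits(countries, "country_raster"))
  sort(unique(countries$ids[countries$valid_mask]))
}
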