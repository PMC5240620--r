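#' Grid geometry for nested fine/coarse lattices
#'
#' Describes a north-up, row-major fine lattice of geographic (lon/lat)
#' pixels together with the integer refinement factor `R` that nests the
#' fine lattice inside a coarse lattice: every coarse cell covers exactly
#' an `R` by `R` block of fine pixels, so `coarse_cell_size = R *
#' fine_cell_size`.  Row 1 is the northernmost row and `(origin_lon,
#' origin_lat)` is the top-left corner of pixel (1, 1).  The published
#' African dataset uses 30 arc-second fine pixels (`1/120` degree) and
#' `R = 60`, i.e. 0.5-degree coarse cells.
#'
#' @param origin_lon,origin_lat top-left corner of the grid, decimal degrees.
#' @param fine_cell_size fine pixel size in degrees (square pixels).
#' @param refinement integer `R >= 1`; fine pixels per coarse cell side.
#' @param n_fine_rows,n_fine_cols fine lattice dimensions; each must be
#'   divisible by `refinement`.
#' @return An object of class `grid_geometry`.
#' @examples
#' g <- grid_geometry(0, 0, 1, refinement = 3, n_fine_rows = 6, n_fine_cols = 9)
#' block_of(g, 2, 3)
#' pixel_center(g, 1, 1)
#' @export
grid_geometry <- function(origin_lon, origin_lat, fine_cell_size,
                          refinement, n_fine_rows, n_fine_cols) {
  stopifnot(
    is.numeric(origin_lon), length(origin_lon) == 1L, is.finite(origin_lon),
    is.numeric(origin_lat), length(origin_lat) == 1L, is.finite(origin_lat),
    is.numeric(fine_cell_size), length(fine_cell_size) == 1L,
    fine_cell_size > 0
  )
  refinement <- as.integer(refinement)
  n_fine_rows <- as.integer(n_fine_rows)
  n_fine_cols <- as.integer(n_fine_cols)
  if (is.na(refinement) || refinement < 1L)
    stop("`refinement` must be an integer >= 1")
  if (n_fine_rows < 1L || n_fine_cols < 1L)
    stop("grid dimensions must be positive")
  if (n_fine_rows %% refinement != 0L || n_fine_cols %% refinement != 0L)
    stop("n_fine_rows and n_fine_cols must each be divisible by `refinement` ",
         "so that coarse cells cover whole R x R fine blocks")
  structure(
    list(origin_lon = as.numeric(origin_lon),
         origin_lat = as.numeric(origin_lat),
         fine_cell_size = as.numeric(fine_cell_size),
         refinement = refinement,
         n_fine_rows = n_fine_rows,
         n_fine_cols = n_fine_cols),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf(
    "<grid_geometry> %d x %d fine pixels of %g deg (R = %d; coarse %d x %d of %g deg)\n",
    x$n_fine_rows, x$n_fine_cols, x$fine_cell_size, x$refinement,
    n_coarse_rows(x), n_coarse_cols(x), coarse_cell_size(x)))
  cat(sprintf("  origin (top-left): lon %g, lat %g; north-up, WGS84 lon/lat\n",
              x$origin_lon, x$origin_lat))
  invisible(x)
}

#' @rdname grid_geometry
#' @param geometry a `grid_geometry`.
#' @export
coarse_cell_size <- function(geometry) geometry$refinement * geometry$fine_cell_size

#' @rdname grid_geometry
#' @export
n_coarse_rows <- function(geometry) geometry$n_fine_rows %/% geometry$refinement

#' @rdname grid_geometry
#' @export
n_coarse_cols <- function(geometry) geometry$n_fine_cols %/% geometry$refinement

#' Fine-pixel block covered by one coarse cell
#'
#' Maps a coarse-cell index to the inclusive range of fine rows and columns
#' it covers.  Blocks over all coarse cells partition the fine lattice
#' exactly: every fine pixel belongs to one and only one block.
#'
#' @param geometry a [grid_geometry()].
#' @param coarse_row,coarse_col 1-based coarse cell indices.
#' @return A list with integer vectors `rows` and `cols` (inclusive ranges).
#' @export
block_of <- function(geometry, coarse_row, coarse_col) {
  R <- geometry$refinement
  if (coarse_row < 1L || coarse_row > n_coarse_rows(geometry) ||
      coarse_col < 1L || coarse_col > n_coarse_cols(geometry))
    stop(sprintf("coarse cell (%d, %d) out of range (%d x %d)",
                 coarse_row, coarse_col,
                 n_coarse_rows(geometry), n_coarse_cols(geometry)))
  list(rows = ((coarse_row - 1L) * R + 1L):(coarse_row * R),
       cols = ((coarse_col - 1L) * R + 1L):(coarse_col * R))
}

#' Geographic centre of a fine pixel
#'
#' Under the north-up convention row 1 is northernmost, so latitude
#' decreases with the row index; the origin is the top-left *corner* of
#' pixel (1, 1) and centres sit half a cell inward.
#'
#' @param geometry a [grid_geometry()].
#' @param row,col 1-based fine pixel indices (vectors allowed, recycled).
#' @return A list with numeric vectors `lon` and `lat` in degrees.
#' @export
pixel_center <- function(geometry, row, col) {
  if (any(row < 1L | row > geometry$n_fine_rows) ||
      any(col < 1L | col > geometry$n_fine_cols))
    stop("pixel index out of range")
  list(lon = geometry$origin_lon + (col - 0.5) * geometry$fine_cell_size,
       lat = geometry$origin_lat - (row - 0.5) * geometry$fine_cell_size)
}

#' Fine pixel containing a geographic point
#'
#' Inverse of [pixel_center()]: returns the (row, col) of the fine pixel
#' whose area contains the point, or `NA` for points outside the grid.
#'
#' @param geometry a [grid_geometry()].
#' @param lon,lat coordinates in degrees (vectors allowed).
#' @return A list with integer vectors `row` and `col` (`NA` outside).
#' @export
pixel_at <- function(geometry, lon, lat) {
  col <- floor((lon - geometry$origin_lon) / geometry$fine_cell_size) + 1
  row <- floor((geometry$origin_lat - lat) / geometry$fine_cell_size) + 1
  bad <- row < 1 | row > geometry$n_fine_rows | col < 1 | col > geometry$n_fine_cols
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Matrices of fine pixel-centre coordinates
#'
#' @param geometry a [grid_geometry()].
#' @return A list of two `n_fine_rows` x `n_fine_cols` matrices `lon`, `lat`.
#' @keywords internal
center_matrices <- function(geometry) {
  lon <- geometry$origin_lon +
    (seq_len(geometry$n_fine_cols) - 0.5) * geometry$fine_cell_size
  lat <- geometry$origin_lat -
    (seq_len(geometry$n_fine_rows) - 0.5) * geometry$fine_cell_size
  list(lon = matrix(lon, geometry$n_fine_rows, geometry$n_fine_cols, byrow = TRUE),
       lat = matrix(lat, geometry$n_fine_rows, geometry$n_fine_cols))
}

#' Coarse-cell index of every fine pixel
#'
#' @return A list of two integer matrices `row`, `col` on the fine lattice.
#' @keywords internal
coarse_index_matrices <- function(geometry) {
  R <- geometry$refinement
  crow <- (seq_len(geometry$n_fine_rows) - 1L) %/% R + 1L
  ccol <- (seq_len(geometry$n_fine_cols) - 1L) %/% R + 1L
  list(row = matrix(crow, geometry$n_fine_rows, geometry$n_fine_cols),
       col = matrix(ccol, geometry$n_fine_rows, geometry$n_fine_cols, byrow = TRUE))
}

same_geometry <- function(a, b, tol = 1e-9) {
  abs(a$origin_lon - b$origin_lon) <= tol &&
    abs(a$origin_lat - b$origin_lat) <= tol &&
    abs(a$fine_cell_size - b$fine_cell_size) <= tol * max(1, a$fine_cell_size) &&
    a$refinement == b$refinement &&
    a$n_fine_rows == b$n_fine_rows &&
    a$n_fine_cols == b$n_fine_cols
}

stop_if_geometry_differs <- function(a, b, what = "grids") {
  if (!same_geometry(a, b))
    stop(what, " do not share the same grid geometry", call. = FALSE)
  invisible(TRUE)
}

# "nearest integer" with halves away from zero, as in the published method;
# banker's rounding would silently change urban pixel counts.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
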