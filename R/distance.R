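#' Euclidean distance from pixel centres to road polylines
#'
#' Computes, for every valid fine pixel, the planar Euclidean distance (in
#' degrees, directly in lon/lat coordinate space) from the pixel centre to
#' the nearest point on any road segment.  Pixels whose centre lies on a
#' road have distance 0.  Planar degree-space distance matches the simple
#' raster tooling traditionally used for such layers; it is a known
#' distortion away from the equator and is acceptable here because the
#' layer is only used, after rescaling to the order of 1e-5 people, to
#' break ranking ties.
#'
#' @param roads a list of polylines; each polyline is a 2-column matrix
#'   (lon, lat) with at least 2 vertices.  See [read_roads_geojson()].
#' @param geometry a [grid_geometry()].
#' @param valid_mask optional logical matrix; distances are computed on
#'   valid pixels only (others are `NA` and flagged invalid).
#' @return A `fine_grid` of distances in degrees.
#' @export
distance_to_roads <- function(roads, geometry, valid_mask = NULL) {
  roads <- check_polylines(roads)
  if (length(roads) == 0L)
    stop("empty road set: the road-distance perturbation layer would be undefined")
  ctr <- center_matrices(geometry)
  if (is.null(valid_mask))
    valid_mask <- matrix(TRUE, geometry$n_fine_rows, geometry$n_fine_cols)
  px <- ctr$lon[valid_mask]
  py <- ctr$lat[valid_mask]
  best <- rep(Inf, length(px))
  for (line in roads) {
    for (i in seq_len(nrow(line) - 1L)) {
      d <- point_segment_distance(px, py,
                                  line[i, 1L], line[i, 2L],
                                  line[i + 1L, 1L], line[i + 1L, 2L])
      best <- pmin(best, d)
    }
  }
  vals <- matrix(NA_real_, geometry$n_fine_rows, geometry$n_fine_cols)
  vals[valid_mask] <- best
  fine_grid(geometry, vals, valid_mask)
}

# distance from points (px, py) to segment (ax, ay)-(bx, by), planar
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

check_polylines <- function(roads) {
  if (is.matrix(roads)) roads <- list(roads)
  stopifnot(is.list(roads))
  for (line in roads) {
    if (!is.matrix(line) || ncol(line) != 2L || nrow(line) < 2L)
      stop("each polyline must be a 2-column (lon, lat) matrix with >= 2 vertices")
    if (any(!is.finite(line))) stop("polyline vertices must be finite")
  }
  roads
}

#' Per-coarse-cell population centres of gravity
#'
#' For every coarse cell the centre of gravity (COG) is the
#' population-weighted mean of the valid fine pixel centres inside the
#' cell.  Cells whose valid pixels carry zero total population fall back
#' to the cell's geometric centre, so a COG is defined for every coarse
#' cell that contains at least one valid pixel (and, for convenience, for
#' fully invalid cells too).
#'
#' @param pop a `fine_grid` of non-negative population counts.
#' @return A data frame with one row per coarse cell: `coarse_row`,
#'   `coarse_col`, `lon`, `lat`, and `weighted` (`FALSE` where the
#'   geometric-centre fallback was used).
#' @export
compute_cogs <- function(pop) {
  stopifnot(inherits(pop, "fine_grid"))
  g <- pop$geometry
  if (any(pop$values[pop$valid_mask] < 0))
    stop("population values must be non-negative")
  ctr <- center_matrices(g)
  nr <- n_coarse_rows(g); nc <- n_coarse_cols(g)
  out <- expand.grid(coarse_row = seq_len(nr), coarse_col = seq_len(nc),
                     KEEP.OUT.ATTRS = FALSE)
  out$lon <- NA_real_; out$lat <- NA_real_; out$weighted <- FALSE
  half <- coarse_cell_size(g) / 2
  for (k in seq_len(nrow(out))) {
    b <- block_of(g, out$coarse_row[k], out$coarse_col[k])
    m <- pop$valid_mask[b$rows, b$cols]
    w <- pop$values[b$rows, b$cols][m]
    if (length(w) > 0L && sum(w) > 0) {
      out$lon[k] <- sum(w * ctr$lon[b$rows, b$cols][m]) / sum(w)
      out$lat[k] <- sum(w * ctr$lat[b$rows, b$cols][m]) / sum(w)
      out$weighted[k] <- TRUE
    } else {
      out$lon[k] <- g$origin_lon + (out$coarse_col[k] - 1) * coarse_cell_size(g) + half
      out$lat[k] <- g$origin_lat - (out$coarse_row[k] - 1) * coarse_cell_size(g) - half
    }
  }
  out
}

#' Distance from each pixel to its own coarse cell's centre of gravity
#'
#' @param cogs a COG table from [compute_cogs()].
#' @param geometry a [grid_geometry()].
#' @param valid_mask optional logical matrix restricting computation.
#' @return A `fine_grid` of planar distances in degrees.
#' @export
distance_to_cog <- function(cogs, geometry, valid_mask = NULL) {
  stopifnot(is.data.frame(cogs),
            all(c("coarse_row", "coarse_col", "lon", "lat") %in% names(cogs)))
  if (is.null(valid_mask))
    valid_mask <- matrix(TRUE, geometry$n_fine_rows, geometry$n_fine_cols)
  ctr <- center_matrices(geometry)
  idx <- coarse_index_matrices(geometry)
  key <- paste(cogs$coarse_row, cogs$coarse_col)
  cog_lon <- matrix(cogs$lon[match(paste(idx$row, idx$col), key)],
                    geometry$n_fine_rows, geometry$n_fine_cols)
  cog_lat <- matrix(cogs$lat[match(paste(idx$row, idx$col), key)],
                    geometry$n_fine_rows, geometry$n_fine_cols)
  if (any(is.na(cog_lon[valid_mask])))
    stop("missing COG for a coarse cell that contains valid pixels")
  vals <- sqrt((ctr$lon - cog_lon)^2 + (ctr$lat - cog_lat)^2)
  vals[!valid_mask] <- NA_real_
  fine_grid(geometry, vals, valid_mask)
}
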