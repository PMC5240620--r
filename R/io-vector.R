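#' Road and border vector input/output (GeoJSON)
#'
#' Roads are LineString/MultiLineString features; country borders are
#' Polygon/MultiPolygon features carrying a `country_id` property.
#' GeoJSON is the package's vector exchange format, written and read
#' with `jsonlite`.
#'
#' @name vector_io
NULL

#' @rdname vector_io
#' @param path a GeoJSON file.
#' @return `read_roads_geojson`: a list of polylines, each a 2-column
#'   (lon, lat) matrix.
#' @export
read_roads_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- geojson_features(gj)
  lines <- list()
  for (f in feats) {
    geom <- f$geometry
    if (is.null(geom)) next
    if (geom$type == "LineString") {
      lines[[length(lines) + 1L]] <- coords_to_matrix(geom$coordinates)
    } else if (geom$type == "MultiLineString") {
      for (part in geom$coordinates)
        lines[[length(lines) + 1L]] <- coords_to_matrix(part)
    } else {
      stop("unsupported road geometry type: ", geom$type)
    }
  }
  check_polylines(lines)
}

#' @rdname vector_io
#' @return `read_countries_geojson`: a list of features, each
#'   `list(country_id, rings)` where `rings` is a list of closed
#'   2-column (lon, lat) ring matrices (exterior and holes; for
#'   MultiPolygon, the rings of all parts).
#' @export
read_countries_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- geojson_features(gj)
  out <- list()
  for (f in feats) {
    id <- f$properties$country_id
    if (is.null(id)) id <- f$properties$id
    if (is.null(id)) stop("country feature missing a country_id property")
    geom <- f$geometry
    rings <- list()
    if (geom$type == "Polygon") {
      for (ring in geom$coordinates)
        rings[[length(rings) + 1L]] <- coords_to_matrix(ring)
    } else if (geom$type == "MultiPolygon") {
      for (poly in geom$coordinates) for (ring in poly)
        rings[[length(rings) + 1L]] <- coords_to_matrix(ring)
    } else {
      stop("unsupported border geometry type: ", geom$type)
    }
    out[[length(out) + 1L]] <- list(country_id = as.integer(id), rings = rings)
  }
  if (length(out) == 0L) stop("no polygon features in ", path)
  out
}

geojson_features <- function(gj) {
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  gj$features
}

coords_to_matrix <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) c(p[[1L]], p[[2L]])))
  storage.mode(m) <- "double"
  m
}

#' @rdname vector_io
#' @param roads list of 2-column (lon, lat) polyline matrices.
#' @export
write_roads_geojson <- function(roads, path) {
  roads <- check_polylines(roads)
  feats <- lapply(roads, function(line) {
    list(type = "Feature", properties = stats::setNames(list(), character(0)),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(line)),
                                              function(i) as.numeric(line[i, ]))))
  })
  write_feature_collection(feats, path)
}

#' @rdname vector_io
#' @param countries list of `list(country_id, rings)` features as
#'   returned by [read_countries_geojson()].
#' @export
write_countries_geojson <- function(countries, path) {
  feats <- lapply(countries, function(f) {
    list(type = "Feature",
         properties = list(country_id = as.integer(f$country_id)),
         geometry = list(
           type = "Polygon",
           coordinates = lapply(f$rings, function(ring)
             lapply(seq_len(nrow(ring)), function(i) as.numeric(ring[i, ])))))
  })
  write_feature_collection(feats, path)
}

write_feature_collection <- function(features, path) {
  obj <- list(type = "FeatureCollection", features = features)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

# even-odd (crossing number) point-in-polygon over a set of rings,
# vectorized over points
points_in_rings <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (ring in rings) {
    n <- nrow(ring)
    x <- ring[, 1L]; y <- ring[, 2L]
    j <- c(n, seq_len(n - 1L))
    for (i in seq_len(n)) {
      xi <- x[i]; yi <- y[i]; xj <- x[j[i]]; yj <- y[j[i]]
      if (yi == yj) next
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
  }
  inside
}

#' Rasterize country polygons onto the fine lattice
#'
#' Assigns each fine pixel the id of the polygon feature containing its
#' centre (even-odd rule, so holes are respected).  Pixels covered by no
#' feature are invalid — water or outside the domain — mirroring a
#' land/water reclassification of national boundaries.  Where features
#' overlap, the later feature wins and a warning is issued.
#'
#' @param countries features as from [read_countries_geojson()].
#' @param geometry a [grid_geometry()].
#' @return A [country_raster()].
#' @export
rasterize_countries <- function(countries, geometry) {
  if (length(countries) == 0L) stop("no country polygons supplied")
  ids <- unlist(lapply(countries, `[[`, "country_id"))
  if (anyDuplicated(ids)) stop("country ids must be unique per feature")
  ctr <- center_matrices(geometry)
  px <- as.numeric(ctr$lon); py <- as.numeric(ctr$lat)
  out <- rep(NA_integer_, length(px))
  overlap_warned <- FALSE
  for (f in countries) {
    inside <- points_in_rings(px, py, f$rings)
    if (!overlap_warned && any(!is.na(out[inside]))) {
      warning("overlapping country polygons: later feature wins")
      overlap_warned <- TRUE
    }
    if (!any(inside))
      warning("country ", f$country_id, " covers no pixel centers")
    out[inside] <- f$country_id
  }
  ids_m <- matrix(out, geometry$n_fine_rows, geometry$n_fine_cols)
  country_raster(geometry, ids_m)
}
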