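#' GeoTIFF input/output
#'
#' Minimal single-band GeoTIFF codec matching the published dataset
#' conventions: uncompressed 32-bit floating point samples (FLT4S),
#' declared nodata -9999, WGS84 geographic (longitude/latitude)
#' referencing via the ModelPixelScale/ModelTiepoint/GeoKey tags.
#' [write_raster()] always emits this exact layout; [read_raster()]
#' additionally accepts big-endian files, multiple strips and integer or
#' double sample formats, and refuses multi-band, tiled, compressed or
#' non-geographic input.
#'
#' @name geotiff
NULL

TIFF_TYPE_SIZES <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8) # BYTE..DOUBLE

#' @rdname geotiff
#' @param grid a `fine_grid` or `coarse_grid`, finite on valid pixels.
#' @param path output file path.
#' @param nodata sentinel written on invalid pixels and declared in the
#'   GDAL nodata tag (default -9999).
#' @return `write_raster` invisibly returns `path`.
#' @export
write_raster <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, c("fine_grid", "coarse_grid")))
  g <- grid$geometry
  if (inherits(grid, "coarse_grid")) {
    cell <- coarse_cell_size(g)
  } else {
    cell <- g$fine_cell_size
  }
  vals <- grid$values
  if (any(!is.finite(vals[grid$valid_mask])))
    stop("grid has non-finite values on valid pixels; cannot serialize")
  vals[!grid$valid_mask] <- nodata
  nr <- nrow(vals); nc <- ncol(vals)

  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w8d <- function(x) writeBin(as.numeric(x), con, size = 8, endian = "little")

  pixel_scale <- c(cell, cell, 0)
  tiepoint <- c(0, 0, 0, g$origin_lon, g$origin_lat, 0)
  # GTModelType = 2 (geographic), GTRasterType = 1 (pixel-is-area),
  # GeographicType = 4326 (WGS84)
  geokeys <- c(1, 1, 0, 3,
               1024, 0, 1, 2,
               1025, 0, 1, 1,
               2048, 0, 1, 4326)
  geoascii <- "WGS 84|"
  nodata_ascii <- as.character(nodata)

  n_entries <- 16L
  ifd_start <- 8L
  ifd_size <- 2L + n_entries * 12L + 4L
  o_scale <- ifd_start + ifd_size
  o_tie <- o_scale + 24L
  o_keys <- o_tie + 48L
  o_ascii <- o_keys + 32L
  len_ascii <- nchar(geoascii) + 1L
  o_nodata <- o_ascii + len_ascii
  len_nodata <- nchar(nodata_ascii) + 1L
  o_strip <- o_nodata + len_nodata
  if (o_strip %% 2L) o_strip <- o_strip + 1L
  strip_bytes <- nr * nc * 4L

  # header
  writeChar("II", con, eos = NULL)
  w2(42L); w4(ifd_start)
  # IFD: entries must be sorted by tag
  entry <- function(tag, type, count, value, inline_size = 2L) {
    w2(tag); w2(type); w4(count)
    if (type == 3L) { w2(value); w2(0L) }         # SHORT inline
    else w4(value)                                 # LONG or offset
  }
  w2(n_entries)
  entry(256L, 4L, 1L, nc)                # ImageWidth
  entry(257L, 4L, 1L, nr)                # ImageLength
  entry(258L, 3L, 1L, 32L)               # BitsPerSample
  entry(259L, 3L, 1L, 1L)                # Compression: none
  entry(262L, 3L, 1L, 1L)                # Photometric: BlackIsZero
  entry(273L, 4L, 1L, o_strip)           # StripOffsets
  entry(277L, 3L, 1L, 1L)                # SamplesPerPixel
  entry(278L, 4L, 1L, nr)                # RowsPerStrip: one strip
  entry(279L, 4L, 1L, strip_bytes)       # StripByteCounts
  entry(284L, 3L, 1L, 1L)                # PlanarConfiguration
  entry(339L, 3L, 1L, 3L)                # SampleFormat: IEEE float
  entry(33550L, 12L, 3L, o_scale)        # ModelPixelScale
  entry(33922L, 12L, 6L, o_tie)          # ModelTiepoint
  entry(34735L, 3L, 16L, o_keys)         # GeoKeyDirectory
  entry(34737L, 2L, len_ascii, o_ascii)  # GeoAsciiParams
  entry(42113L, 2L, len_nodata, o_nodata) # GDAL_NODATA
  w4(0L)                                 # next IFD: none
  # external values
  w8d(pixel_scale)
  w8d(tiepoint)
  w2(geokeys)
  writeBin(c(charToRaw(geoascii), as.raw(0L)), con)
  writeBin(c(charToRaw(nodata_ascii), as.raw(0L)), con)
  if ((seek(con) %% 2L) != 0L) writeBin(as.raw(0L), con)
  # pixel data, row-major from the north
  writeBin(as.numeric(t(vals)), con, size = 4, endian = "little")
  invisible(path)
}

read_tiff_ifd <- function(con, endian) {
  r2 <- function(n = 1L) readBin(con, "integer", n, size = 2, signed = FALSE,
                                 endian = endian)
  r4 <- function(n = 1L) readBin(con, "integer", n, size = 4, endian = endian)
  n <- r2()
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    tag <- r2(); type <- r2(); count <- r4()
    raw_value <- readBin(con, "raw", 4L)
    entries[[i]] <- list(tag = tag, type = type, count = count,
                         raw_value = raw_value)
  }
  next_ifd <- r4()
  list(entries = entries, next_ifd = next_ifd)
}

read_tag_values <- function(con, e, endian) {
  size <- TIFF_TYPE_SIZES[e$type] * e$count
  if (size <= 4L) {
    raw <- e$raw_value[seq_len(size)]
  } else {
    offset <- readBin(e$raw_value, "integer", 1L, size = 4, endian = endian)
    seek(con, offset)
    raw <- readBin(con, "raw", size)
  }
  switch(as.character(e$type),
    "2" = rawToChar(raw[raw != as.raw(0L)]),
    "3" = readBin(raw, "integer", e$count, size = 2, signed = FALSE, endian = endian),
    "4" = readBin(raw, "integer", e$count, size = 4, endian = endian),
    "11" = readBin(raw, "double", e$count, size = 4, endian = endian),
    "12" = readBin(raw, "double", e$count, size = 8, endian = endian),
    readBin(raw, "integer", e$count, size = 1, signed = FALSE)
  )
}

read_geotiff_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  order_bytes <- readChar(con, 2L, useBytes = TRUE)
  endian <- switch(order_bytes, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  magic <- readBin(con, "integer", 1L, size = 2, signed = FALSE, endian = endian)
  if (magic != 42L) stop("not a TIFF file (bad magic): ", path)
  ifd_offset <- readBin(con, "integer", 1L, size = 4, endian = endian)
  seek(con, ifd_offset)
  ifd <- read_tiff_ifd(con, endian)
  tags <- lapply(ifd$entries, read_tag_values, con = con, endian = endian)
  names(tags) <- vapply(ifd$entries, `[[`, numeric(1), "tag")
  types <- vapply(ifd$entries, `[[`, numeric(1), "type")
  names(types) <- names(tags)
  if (ifd$next_ifd != 0L)
    stop("multi-image TIFF not supported: ", path)

  get <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) default else v
  }
  nc <- get(256); nr <- get(257)
  if (is.null(nc) || is.null(nr)) stop("TIFF missing image dimensions")
  if (!is.null(get(322)) || !is.null(get(323)))
    stop("tiled TIFF not supported: ", path)
  if (get(259, 1L) != 1L) stop("compressed TIFF not supported: ", path)
  spp <- get(277, 1L)
  if (spp != 1L)
    stop("multi-band raster not supported (", spp, " samples per pixel): ", path)
  bits <- get(258, 1L)
  fmt <- get(339, 1L)
  strip_offsets <- get(273)
  strip_counts <- get(279)
  if (is.null(strip_offsets) || is.null(strip_counts))
    stop("TIFF missing strip layout")

  raw <- raw(0)
  for (i in seq_along(strip_offsets)) {
    seek(con, strip_offsets[i])
    raw <- c(raw, readBin(con, "raw", strip_counts[i]))
  }
  vals <- if (fmt == 3L && bits == 32L) {
    readBin(raw, "double", nr * nc, size = 4, endian = endian)
  } else if (fmt == 3L && bits == 64L) {
    readBin(raw, "double", nr * nc, size = 8, endian = endian)
  } else if (fmt %in% c(1L, 2L) && bits %in% c(8L, 16L, 32L)) {
    readBin(raw, "integer", nr * nc, size = bits %/% 8L,
            signed = !(fmt == 1L && bits < 32L), endian = endian)
  } else {
    stop("unsupported sample format (format ", fmt, ", ", bits, " bits)")
  }
  values <- matrix(as.numeric(vals), nr, nc, byrow = TRUE)

  geokeys <- get(34735)
  model_type <- NA_integer_
  if (!is.null(geokeys) && length(geokeys) >= 4L) {
    keys <- matrix(geokeys[-(1:4)], ncol = 4L, byrow = TRUE)
    hit <- which(keys[, 1L] == 1024L)
    if (length(hit)) model_type <- keys[hit[1L], 4L]
  }
  if (is.na(model_type) || model_type != 2L)
    stop("raster is not geographically referenced (need lon/lat WGS84): ", path)
  scale <- get(33550)
  tie <- get(33922)
  if (is.null(scale) || is.null(tie))
    stop("raster missing ModelPixelScale/ModelTiepoint georeferencing: ", path)
  nodata <- suppressWarnings(as.numeric(get(42113, NA_character_)))

  list(values = values,
       origin_lon = tie[4L] - tie[1L] * scale[1L],
       origin_lat = tie[5L] + tie[2L] * scale[2L],
       cell_size_lon = scale[1L], cell_size_lat = scale[2L],
       nodata = nodata, n_rows = nr, n_cols = nc,
       bits_per_sample = bits, sample_format = fmt,
       geographic = TRUE)
}

#' @rdname geotiff
#' @param geometry optional run [grid_geometry()]; when supplied, a file
#'   that does not align exactly is resampled onto the run lattice by
#'   nearest neighbour with a logged notice.
#' @param role `"fine"` to interpret the file on the fine lattice,
#'   `"coarse"` for the coarse (urban-fraction) lattice of `geometry`.
#' @param refinement refinement factor attached when reading without a
#'   run geometry (default 1).
#' @return `read_raster` returns a `fine_grid` (`role = "fine"`) or
#'   `coarse_grid` (`role = "coarse"`); nodata pixels become invalid.
#' @export
read_raster <- function(path, geometry = NULL, role = c("fine", "coarse"),
                        refinement = 1L) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read_geotiff_raw(path)
  mask <- if (is.na(raw$nodata)) {
    !is.na(raw$values)
  } else {
    !is.na(raw$values) & raw$values != raw$nodata
  }
  vals <- raw$values
  vals[!mask] <- NA_real_

  if (is.null(geometry)) {
    if (role == "coarse")
      stop("reading a coarse grid requires the run `geometry`")
    g <- grid_geometry(raw$origin_lon, raw$origin_lat, raw$cell_size_lon,
                       refinement, raw$n_rows, raw$n_cols)
    return(fine_grid(g, vals, mask, check = FALSE))
  }

  if (role == "fine") {
    target <- list(origin_lon = geometry$origin_lon,
                   origin_lat = geometry$origin_lat,
                   cell = geometry$fine_cell_size,
                   nr = geometry$n_fine_rows, nc = geometry$n_fine_cols)
  } else {
    target <- list(origin_lon = geometry$origin_lon,
                   origin_lat = geometry$origin_lat,
                   cell = coarse_cell_size(geometry),
                   nr = n_coarse_rows(geometry), nc = n_coarse_cols(geometry))
  }
  aligned <- raster_aligned(raw, target)
  if (!aligned) {
    message("raster ", path, " does not align with the run geometry; ",
            "resampling by nearest neighbour")
    res <- resample_nearest(vals, mask, raw, target)
    vals <- res$values; mask <- res$mask
  }
  if (role == "fine") fine_grid(geometry, vals, mask, check = FALSE)
  else coarse_grid(geometry, vals, mask, check = FALSE)
}

raster_aligned <- function(raw, target, tol = 1e-9) {
  abs(raw$origin_lon - target$origin_lon) <= tol &&
    abs(raw$origin_lat - target$origin_lat) <= tol &&
    abs(raw$cell_size_lon - target$cell) <= tol &&
    abs(raw$cell_size_lat - target$cell) <= tol &&
    raw$n_rows == target$nr && raw$n_cols == target$nc
}

resample_nearest <- function(vals, mask, raw, target) {
  lon <- target$origin_lon + (seq_len(target$nc) - 0.5) * target$cell
  lat <- target$origin_lat - (seq_len(target$nr) - 0.5) * target$cell
  src_col <- floor((lon - raw$origin_lon) / raw$cell_size_lon) + 1
  src_row <- floor((raw$origin_lat - lat) / raw$cell_size_lat) + 1
  out <- matrix(NA_real_, target$nr, target$nc)
  outm <- matrix(FALSE, target$nr, target$nc)
  ok_col <- src_col >= 1 & src_col <= raw$n_cols
  ok_row <- src_row >= 1 & src_row <= raw$n_rows
  for (i in which(ok_row)) {
    out[i, ok_col] <- vals[src_row[i], src_col[ok_col]]
    outm[i, ok_col] <- mask[src_row[i], src_col[ok_col]]
  }
  out[!outm] <- NA_real_
  list(values = out, mask = outm)
}
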