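# Plain-text GIS I/O.
#
# Vector layers are GeoJSON FeatureCollections carrying a legacy named
# "crs" member (projected CRS required -- all computations are planar
# metres). Rasters are single-band ESRI ASCII grids (.asc), a text format
# with a 5-6 line header followed by rows of cell values, north row
# first; the CRS travels as an argument or an accompanying convention.

.geomFromGeoJSON <- function(geom) {
  if (is.null(geom)) stop("feature without geometry", call. = FALSE)
  ringmat <- function(ring)
    do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  if (geom$type == "Polygon") {
    lapply(geom$coordinates, ringmat)
  } else if (geom$type == "MultiPolygon") {
    unlist(lapply(geom$coordinates,
                  function(poly) lapply(poly, ringmat)), recursive = FALSE)
  } else {
    stop("unsupported geometry type '", geom$type,
         "'; only Polygon and MultiPolygon are handled", call. = FALSE)
  }
}

.geomToGeoJSON <- function(g) {
  rings <- lapply(.asGeom(g), function(r) {
    r <- rbind(r, r[1, ])            # GeoJSON rings are closed
    lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
  })
  list(type = "Polygon", coordinates = rings)
}

.readFeatureCollection <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$type) || doc$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  crs <- doc$crs$properties$name
  if (is.null(crs)) {
    warning("no 'crs' member in ", basename(path),
            "; assuming a projected CRS in metres", call. = FALSE)
    crs <- "unknown-projected"
  }
  .checkProjectedCRS(crs)
  feats <- doc$features
  props <- lapply(feats, function(f) f$properties)
  keys <- unique(unlist(lapply(props, names)))
  cols <- lapply(keys, function(k) {
    vals <- lapply(props, function(p) if (is.null(p[[k]])) NA else p[[k]])
    unlist(vals)
  })
  names(cols) <- keys
  d <- if (length(keys)) as.data.frame(cols, stringsAsFactors = FALSE,
                                       optional = TRUE)
       else data.frame(row.names = seq_along(feats))
  geometry <- lapply(feats, function(f) .geomFromGeoJSON(f$geometry))
  list(data = d, geometry = geometry, crs = crs)
}

.writeFeatureCollection <- function(data, geometry, crs, path) {
  feats <- lapply(seq_len(nrow(data)), function(i) {
    list(type = "Feature",
         properties = as.list(data[i, , drop = FALSE]),
         geometry = .geomToGeoJSON(geometry[[i]]))
  })
  doc <- list(type = "FeatureCollection",
              crs = list(type = "name", properties = list(name = crs)),
              features = feats)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = 10,
                           null = "null")
  ok <- tryCatch({ writeLines(json, path); TRUE },
                 error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}

#' Read an urban representation from GeoJSON
#'
#' Expects the standard element attributes (`land_use`,
#' `land_use_verbose`, `floors`, `area`, `flat_area`, `edible_area`).
#' `land_use`, `floors` and `area` are mandatory; a missing `edible_area`
#' is filled with 0 and a missing `flat_area` with `area`.
#'
#' @param path path to a GeoJSON FeatureCollection in a projected CRS.
#' @return A [CityModel-class].
#' @export
readCity <- function(path) {
  fc <- .readFeatureCollection(path)
  if (nrow(fc$data) == 0)            # schema is vacuous without features
    return(cityModel(data.frame(land_use = character(0),
                                floors = numeric(0), area = numeric(0)),
                     list(), crs = fc$crs))
  miss <- setdiff(c("land_use", "floors", "area"), names(fc$data))
  if (length(miss))
    stop("mandatory column(s) missing in ", basename(path), ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  cityModel(fc$data, fc$geometry, crs = fc$crs)
}

#' Write an urban representation to GeoJSON
#'
#' The emitted file is re-readable by [readCity()]; attributes and
#' coordinates round-trip (coordinates to ~1e-6 m).
#'
#' @param city a [CityModel-class].
#' @param path output path (overwritten when present).
#' @return `path`, invisibly.
#' @export
writeCity <- function(city, path) {
  stopifnot(is(city, "CityModel"))
  .writeFeatureCollection(city@data, city@geometry, city@crs, path)
}

#' Read a neighbourhood layer from GeoJSON
#'
#' @param path GeoJSON FeatureCollection with `name` and `inhabitants`
#'   properties.
#' @param name_col,inh_col property names holding the neighbourhood name
#'   and population.
#' @return A [NeighbourhoodLayer-class].
#' @export
readNeighbourhoods <- function(path, name_col = "name",
                               inh_col = "inhabitants") {
  fc <- .readFeatureCollection(path)
  miss <- setdiff(c(name_col, inh_col), names(fc$data))
  if (length(miss))
    stop("mandatory column(s) missing in ", basename(path), ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  neighbourhoodLayer(fc$data[[name_col]], fc$data[[inh_col]],
                     fc$geometry, crs = fc$crs)
}

#' @rdname readNeighbourhoods
#' @param nb a [NeighbourhoodLayer-class] to write.
#' @export
writeNeighbourhoods <- function(nb, path) {
  stopifnot(is(nb, "NeighbourhoodLayer"))
  .writeFeatureCollection(nb@data, nb@geometry, nb@crs, path)
}

.readAsciiGrid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 6)
  hdr <- list()
  nheader <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && is.na(suppressWarnings(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      nheader <- nheader + 1
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("not an ESRI ASCII grid (header lacks ",
         paste(miss, collapse = ", "), "): ", path, call. = FALSE)
  vals <- scan(path, skip = nheader, quiet = TRUE)
  nc <- hdr$ncols; nr <- hdr$nrows
  if (length(vals) != nc * nr)
    stop("raster format error: expected ", nc * nr, " cells, found ",
         length(vals), " (multi-band or truncated file?)", call. = FALSE)
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  list(values = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellsize = hdr$cellsize)
}

#' Read a sky-view-factor raster (ESRI ASCII grid)
#'
#' Values must be fractions of visible sky in `[0, 1]`; nodata cells are
#' preserved as `NA` and excluded from every later mean. If more than 1%
#' of the finite cells fall outside `[0, 1]` the file is rejected;
#' smaller numeric excursions are clipped into range.
#'
#' @param path path to a single-band `.asc` file.
#' @param crs projected CRS the grid is referenced in (the ASCII grid
#'   format does not carry one).
#' @return An [SvfGrid-class].
#' @export
readSvf <- function(path, crs = "EPSG:25831") {
  g <- .readAsciiGrid(path)
  v <- g$values
  fin <- is.finite(v)
  out <- fin & (v < 0 | v > 1)
  if (sum(out) > 0.01 * max(1, sum(fin)))
    stop("more than 1% of finite cells lie outside [0, 1]; ",
         "not a sky-view-factor raster: ", path, call. = FALSE)
  v[fin] <- pmin(1, pmax(0, v[fin]))
  rasterGrid(v, g$xll, g$yll, g$cellsize, crs = crs, svf = TRUE)
}

#' Write a raster grid as an ESRI ASCII grid
#'
#' @param grid a [RasterGrid-class] (or [SvfGrid-class]).
#' @param path output `.asc` path.
#' @param nodata value written for `NA` cells.
#' @param digits significant digits for cell values.
#' @return `path`, invisibly.
#' @export
writeRasterGrid <- function(grid, path, nodata = -9999, digits = 8) {
  stopifnot(is(grid, "RasterGrid"))
  v <- grid@values
  hdr <- c(paste("ncols", ncol(v)), paste("nrows", nrow(v)),
           paste("xllcorner", format(grid@xll, scientific = FALSE)),
           paste("yllcorner", format(grid@yll, scientific = FALSE)),
           paste("cellsize", format(grid@cellsize, scientific = FALSE)),
           paste("NODATA_value", nodata))
  v[!is.finite(v)] <- nodata
  rows <- apply(signif(v, digits), 1, paste, collapse = " ")
  ok <- tryCatch({ writeLines(c(hdr, rows), path); TRUE },
                 error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}
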