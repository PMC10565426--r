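#' @import methods
NULL

# Geographic (degree-unit) CRS identifiers we refuse to compute on. All
# package maths assumes planar metre coordinates.
.GEOGRAPHIC_CRS <- c("EPSG:4326", "EPSG:4258", "CRS84", "OGC:CRS84",
                     "urn:ogc:def:crs:OGC:1.3:CRS84",
                     "urn:ogc:def:crs:EPSG::4326")

.checkProjectedCRS <- function(crs) {
  if (toupper(crs) %in% toupper(.GEOGRAPHIC_CRS)) {
    stop("CRS '", crs, "' is geographic (degree units); ",
         "reproject the layer to a projected CRS in metres.", call. = FALSE)
  }
  invisible(crs)
}

.CITY_COLUMNS <- c("id", "land_use", "land_use_verbose", "floors",
                   "area", "flat_area", "edible_area")

#' City model: a polygon representation of urban elements
#'
#' An ordered collection of urban elements (buildings, gardens, streets,
#' vacant plots, parks, ...), each a polygon in a projected metric CRS
#' with the attributes every indicator consumes: `land_use`,
#' `land_use_verbose`, `floors`, `area` (m2), `flat_area` (m2 with slope
#' below 5 degrees) and `edible_area` (m2 used to grow edible plants;
#' 0 for elements that are not urban-agriculture solutions).
#'
#' @slot data data.frame with one row per element and the columns above
#'   plus a unique `id`.
#' @slot geometry list of geometries parallel to `data`; each geometry is
#'   a list of n x 2 vertex matrices (rings) under the even-odd rule.
#' @slot crs character CRS descriptor, e.g. `"EPSG:25831"`; must be
#'   projected with metre units.
#' @export
setClass("CityModel",
  representation(data = "data.frame", geometry = "list", crs = "character"),
  validity = function(object) {
    msg <- character(0)
    d <- object@data
    miss <- setdiff(.CITY_COLUMNS, names(d))
    if (length(miss))
      msg <- c(msg, paste0("missing column(s): ", paste(miss, collapse = ", ")))
    if (length(object@geometry) != nrow(d))
      msg <- c(msg, "geometry list length differs from number of rows")
    if (!length(msg) && nrow(d)) {
      if (anyDuplicated(d$id)) msg <- c(msg, "element ids are not unique")
      if (any(d$floors < 0)) msg <- c(msg, "floors must be >= 0")
      if (any(d$area <= 0)) msg <- c(msg, "area must be > 0")
      if (any(d$flat_area < 0 | d$flat_area > d$area * (1 + 1e-9)))
        msg <- c(msg, "flat_area must lie in [0, area]")
      if (any(d$edible_area < 0 | d$edible_area > d$area * (1 + 1e-9)))
        msg <- c(msg, "edible_area must lie in [0, area]")
      nv <- vapply(object@geometry,
                   function(g) all(vapply(.asGeom(g), nrow, 0L) >= 3), TRUE)
      if (!all(nv)) msg <- c(msg, "all rings need at least 3 vertices")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a CityModel
#'
#' Fills optional attributes with their documented defaults: a missing
#' `edible_area` becomes 0, a missing `flat_area` becomes `area`, a
#' missing `area` is recomputed from the geometry. When a supplied `area`
#' disagrees with the recomputed polygon area by more than 5% a warning
#' is raised (the attribute value is kept).
#'
#' @param data data.frame with at least `land_use` and `floors` (plus
#'   `area` unless geometries are given).
#' @param geometry list of geometries (ring matrices or lists of rings).
#' @param crs projected CRS descriptor (metres).
#' @return A validated [CityModel-class] object.
#' @export
cityModel <- function(data, geometry, crs = "EPSG:25831") {
  .checkProjectedCRS(crs)
  data <- as.data.frame(data)
  geometry <- lapply(geometry, .asGeom)
  mandatory <- c("land_use", "floors")
  miss <- setdiff(mandatory, names(data))
  if (length(miss))
    stop("mandatory column(s) missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  geomArea <- vapply(geometry, .geomArea, numeric(1))
  if (!"area" %in% names(data)) data$area <- geomArea
  n <- nrow(data)
  if (!"id" %in% names(data)) data$id <- seq_len(n)
  if (!"land_use_verbose" %in% names(data))
    data$land_use_verbose <- character(n)
  if (!"flat_area" %in% names(data)) data$flat_area <- data$area
  if (!"edible_area" %in% names(data)) data$edible_area <- numeric(n)
  if (nrow(data)) {
    rel <- abs(geomArea - data$area) / data$area
    bad <- which(rel > 0.05)
    if (length(bad))
      warning(length(bad), " element(s) have an 'area' attribute differing ",
              "from the recomputed polygon area by more than 5%",
              call. = FALSE)
  }
  data <- data[, union(.CITY_COLUMNS, names(data)), drop = FALSE]
  rownames(data) <- NULL
  new("CityModel", data = data, geometry = geometry, crs = crs)
}

#' Regular north-up raster grid
#'
#' A matrix of cell values with lower-left corner georeferencing, the
#' plain-text ESRI ASCII grid model. Row 1 of `values` is the TOP row of
#' the grid (north), matching file order.
#'
#' @slot values numeric matrix (NA = nodata).
#' @slot xll,yll coordinates of the lower-left corner of the grid.
#' @slot cellsize cell edge length in metres.
#' @slot crs projected CRS descriptor.
#' @export
setClass("RasterGrid",
  representation(values = "matrix", xll = "numeric", yll = "numeric",
                 cellsize = "numeric", crs = "character"),
  validity = function(object) {
    if (object@cellsize <= 0) return("cellsize must be > 0")
    TRUE
  })

#' Sky-view-factor grid
#'
#' A [RasterGrid-class] whose finite values are fractions of unobstructed
#' sky hemisphere, constrained to `[0, 1]`. Also used for vegetation
#' fraction grids, which obey the same range.
#' @export
setClass("SvfGrid", contains = "RasterGrid",
  validity = function(object) {
    v <- object@values[is.finite(object@values)]
    if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
      return("finite SVF values must lie in [0, 1]")
    TRUE
  })

#' @rdname RasterGrid-class
#' @param values,xll,yll,cellsize,crs see slots.
#' @param svf logical; when `TRUE` return an [SvfGrid-class] (values
#'   checked against `[0, 1]`).
#' @export
rasterGrid <- function(values, xll = 0, yll = 0, cellsize = 1,
                       crs = "EPSG:25831", svf = FALSE) {
  .checkProjectedCRS(crs)
  new(if (svf) "SvfGrid" else "RasterGrid",
      values = as.matrix(values), xll = as.numeric(xll)[1],
      yll = as.numeric(yll)[1], cellsize = as.numeric(cellsize)[1],
      crs = crs)
}

#' Neighbourhood layer
#'
#' Polygons with a unique `name` and an `inhabitants` count, used by the
#' green-per-capita equity indicator.
#' @slot data data.frame with columns `name` and `inhabitants`.
#' @slot geometry list of geometries parallel to `data`.
#' @slot crs projected CRS descriptor.
#' @export
setClass("NeighbourhoodLayer",
  representation(data = "data.frame", geometry = "list", crs = "character"),
  validity = function(object) {
    d <- object@data
    if (!all(c("name", "inhabitants") %in% names(d)))
      return("need columns 'name' and 'inhabitants'")
    if (anyDuplicated(d$name)) return("neighbourhood names must be unique")
    if (any(d$inhabitants < 0)) return("inhabitants must be >= 0")
    if (length(object@geometry) != nrow(d))
      return("geometry list length differs from number of rows")
    TRUE
  })

#' @rdname NeighbourhoodLayer-class
#' @param name character vector of unique names.
#' @param inhabitants integer vector of population counts.
#' @param geometry list of geometries.
#' @param crs projected CRS descriptor.
#' @export
neighbourhoodLayer <- function(name, inhabitants, geometry,
                               crs = "EPSG:25831") {
  .checkProjectedCRS(crs)
  new("NeighbourhoodLayer",
      data = data.frame(name = as.character(name),
                        inhabitants = as.numeric(inhabitants)),
      geometry = lapply(geometry, .asGeom), crs = crs)
}

#' Six-number summary
#'
#' min, first quartile, median, mean, third quartile, max of a set of
#' values (quantiles by linear interpolation, the type-7 convention).
#' @export
setClass("SummaryStats",
  representation(min = "numeric", q25 = "numeric", median = "numeric",
                 mean = "numeric", q75 = "numeric", max = "numeric"),
  validity = function(object) {
    v <- c(object@min, object@q25, object@median, object@q75, object@max)
    if (is.unsorted(v, strictly = FALSE)) return("quantiles out of order")
    if (object@mean < object@min - 1e-12 || object@mean > object@max + 1e-12)
      return("mean outside [min, max]")
    TRUE
  })

#' Monte-Carlo interval estimate
#'
#' Lower and upper empirical quantiles plus the median of a set of
#' simulated totals; `level` is the nominal two-sided coverage.
#' @export
setClass("IntervalEstimate",
  representation(lower = "numeric", median = "numeric", upper = "numeric",
                 level = "numeric"),
  validity = function(object) {
    if (object@lower > object@median || object@median > object@upper)
      return("need lower <= median <= upper")
    if (object@level <= 0 || object@level >= 1)
      return("level must be in (0, 1)")
    TRUE
  })

#' @export
setMethod("$", "IntervalEstimate", function(x, name) slot(x, name))

#' Scenario parameters
#'
#' All knobs of [setScenario()]: the proportion of candidate private
#' gardens / vacant plots / rooftops to convert, the uniform range the
#' per-element edible fraction is drawn from, minimum areas, source land
#' uses, the commercial share and the attribute used as available
#' surface.
#' @export
setClass("ScenarioParams",
  representation(pGardens = "numeric", pVacant = "numeric",
                 pRooftop = "numeric",
                 edible_area_garden = "numeric",
                 edible_area_vacant = "numeric",
                 edible_area_rooftop = "numeric",
                 min_area_garden = "numeric", min_area_vacant = "numeric",
                 min_area_rooftop = "numeric",
                 private_gardens_from = "character",
                 vacant_from = "character", rooftop_from = "character",
                 pCommercial = "numeric", area_field = "character",
                 quiet = "logical"),
  prototype(pGardens = 1, pVacant = 1, pRooftop = 1,
            edible_area_garden = c(0.02, 0.3),
            edible_area_vacant = c(0.52, 0.75),
            edible_area_rooftop = c(0.6, 0.62),
            min_area_garden = 10, min_area_vacant = 100,
            min_area_rooftop = 100,
            private_gardens_from = "Normal garden",
            vacant_from = "Vacant", rooftop_from = "Rooftop",
            pCommercial = 0, area_field = "flat_area", quiet = FALSE),
  validity = function(object) {
    p <- c(object@pGardens, object@pVacant, object@pRooftop,
           object@pCommercial)
    if (any(p < 0 | p > 1)) return("proportions must lie in [0, 1]")
    for (r in list(object@edible_area_garden, object@edible_area_vacant,
                   object@edible_area_rooftop)) {
      if (length(r) != 2 || r[1] > r[2] || r[1] < 0 || r[2] > 1)
        return("edible_area ranges must be [lo, hi] within [0, 1]")
    }
    if (any(c(object@min_area_garden, object@min_area_vacant,
              object@min_area_rooftop) < 0))
      return("minimum areas must be >= 0")
    TRUE
  })

#' @rdname ScenarioParams-class
#' @param ... slot values overriding the defaults (which mirror the
#'   scenario-generator call signature: `pGardens = 1`, `pVacant = 1`,
#'   `pRooftop = 1`, `edible_area_garden = c(0.02, 0.3)`,
#'   `edible_area_vacant = c(0.52, 0.75)`,
#'   `edible_area_rooftop = c(0.6, 0.62)`, minimum areas 10/100/100 m2,
#'   sources "Normal garden"/"Vacant"/"Rooftop", `pCommercial = 0`,
#'   `area_field = "flat_area"`).
#' @export
scenarioParams <- function(...) new("ScenarioParams", ...)

#' Urban-heat-island meteorological parameters
#'
#' Defaults describe a Mediterranean summer reference day: daily average
#' global radiation `Qql` (W/m2/hour), air heat capacity `Cair` (J/kg/K),
#' air density `Pair` (kg/m3), daily maximum and minimum average
#' temperature (degrees C) and average wind speed (m/s).
#' @export
setClass("UhiParams",
  representation(Qql = "numeric", Cair = "numeric", Pair = "numeric",
                 Tmax = "numeric", Tmin = "numeric", windspeed = "numeric"),
  prototype(Qql = 6.11, Cair = 1007, Pair = 1.14, Tmax = 30.8, Tmin = 20,
            windspeed = 2.77),
  validity = function(object) {
    if (object@Tmax < object@Tmin) return("Tmax must be >= Tmin")
    if (any(c(object@Qql, object@Cair, object@Pair, object@windspeed) <= 0))
      return("Qql, Cair, Pair and windspeed must be > 0")
    TRUE
  })

#' @rdname UhiParams-class
#' @param ... slot values overriding the defaults.
#' @export
uhiParams <- function(...) new("UhiParams", ...)

#' Runoff parameters
#'
#' `rain` is the 24-hour design storm depth in mm; `harvest_dist` the
#' maximum distance (m) at which a taller building counts as a harvest
#' catchment; `tank_size` the uniform range (litres per m2 of element
#' surface) the storage-tank size is drawn from.
#' @export
setClass("RunoffParams",
  representation(rain = "numeric", floors_field = "character",
                 harvest_dist = "numeric", tank_size = "numeric"),
  prototype(rain = 85, floors_field = "floors", harvest_dist = 10,
            tank_size = c(0, 45)),
  validity = function(object) {
    if (object@rain < 0) return("rain must be >= 0")
    if (object@harvest_dist < 0) return("harvest_dist must be >= 0")
    t <- object@tank_size
    if (length(t) != 2 || t[1] > t[2] || t[1] < 0)
      return("tank_size must be [lo, hi] with 0 <= lo <= hi")
    TRUE
  })

#' @rdname RunoffParams-class
#' @param ... slot values overriding the defaults.
#' @export
runoffParams <- function(...) new("RunoffParams", ...)

#' Synthetic-city generator configuration
#'
#' A rectangular grid of `blocks_x` by `blocks_y` square blocks of
#' `block_size` metres separated by streets of `street_width` metres.
#' Blocks are assigned land uses according to the four fractions (the
#' remainder, if any, becomes extra street blocks).
#' @export
setClass("SyntheticConfig",
  representation(blocks_x = "numeric", blocks_y = "numeric",
                 block_size = "numeric", street_width = "numeric",
                 building_fraction = "numeric", vacant_fraction = "numeric",
                 garden_fraction = "numeric", park_fraction = "numeric",
                 floors_range = "numeric",
                 inhabitants_per_residence = "numeric", seed = "numeric"),
  prototype(blocks_x = 12, blocks_y = 12, block_size = 80, street_width = 8,
            building_fraction = 0.5, vacant_fraction = 0.12,
            garden_fraction = 0.18, park_fraction = 0.12,
            floors_range = c(1, 6), inhabitants_per_residence = 40,
            seed = 1L),
  validity = function(object) {
    f <- c(object@building_fraction, object@vacant_fraction,
           object@garden_fraction, object@park_fraction)
    if (any(f < 0)) return("fractions must be >= 0")
    if (sum(f) > 1 + 1e-9) return("fractions must sum to <= 1")
    if (object@blocks_x < 1 || object@blocks_y < 1)
      return("grid dimensions must be >= 1")
    if (object@block_size <= 0) return("block_size must be > 0")
    if (object@street_width < 0) return("street_width must be >= 0")
    if (length(object@floors_range) != 2 ||
        object@floors_range[1] > object@floors_range[2] ||
        object@floors_range[1] < 0)
      return("floors_range must be [lo, hi] with 0 <= lo <= hi")
    TRUE
  })

#' @rdname SyntheticConfig-class
#' @param ... slot values overriding the defaults.
#' @export
syntheticConfig <- function(...) new("SyntheticConfig", ...)
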