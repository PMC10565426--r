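#' Number of elements in a spatial collection
#' @param x a [CityModel-class] or [NeighbourhoodLayer-class].
#' @return integer count.
#' @export
setGeneric("nElements", function(x) standardGeneric("nElements"))

#' Attribute table of a spatial collection
#' @param x a [CityModel-class] or [NeighbourhoodLayer-class].
#' @return the data.frame of per-element attributes.
#' @export
setGeneric("elements", function(x) standardGeneric("elements"))

#' Geometry list of a spatial collection
#' @param x a [CityModel-class] or [NeighbourhoodLayer-class].
#' @return list of geometries (lists of ring matrices).
#' @export
setGeneric("geometries", function(x) standardGeneric("geometries"))

#' Coordinate reference system descriptor
#' @param x a spatial object.
#' @return character CRS string.
#' @export
setGeneric("crsName", function(x) standardGeneric("crsName"))

#' Geometric areas of the elements (m2)
#' @param x a [CityModel-class] or [NeighbourhoodLayer-class].
#' @return numeric vector of polygon areas recomputed from the geometry.
#' @export
setGeneric("geomAreas", function(x) standardGeneric("geomAreas"))

#' @rdname nElements
#' @export
setMethod("nElements", "CityModel", function(x) nrow(x@data))
#' @rdname nElements
#' @export
setMethod("nElements", "NeighbourhoodLayer", function(x) nrow(x@data))

#' @rdname elements
#' @export
setMethod("elements", "CityModel", function(x) x@data)
#' @rdname elements
#' @export
setMethod("elements", "NeighbourhoodLayer", function(x) x@data)

#' @rdname geometries
#' @export
setMethod("geometries", "CityModel", function(x) x@geometry)
#' @rdname geometries
#' @export
setMethod("geometries", "NeighbourhoodLayer", function(x) x@geometry)

#' @rdname crsName
#' @export
setMethod("crsName", "CityModel", function(x) x@crs)
#' @rdname crsName
#' @export
setMethod("crsName", "NeighbourhoodLayer", function(x) x@crs)
#' @rdname crsName
#' @export
setMethod("crsName", "RasterGrid", function(x) x@crs)

#' @rdname geomAreas
#' @export
setMethod("geomAreas", "CityModel",
          function(x) vapply(x@geometry, .geomArea, numeric(1)))
#' @rdname geomAreas
#' @export
setMethod("geomAreas", "NeighbourhoodLayer",
          function(x) vapply(x@geometry, .geomArea, numeric(1)))

#' Grid values of a raster
#' @param x a [RasterGrid-class].
#' @return numeric matrix (row 1 = north).
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname gridValues
#' @export
setMethod("gridValues", "RasterGrid", function(x) x@values)

#' Coordinates of raster cell centres
#' @param x a [RasterGrid-class].
#' @return list with numeric vectors `x` (west to east) and `y` (north to
#'   south, matching row order of [gridValues()]).
#' @export
setGeneric("cellCentres", function(x) standardGeneric("cellCentres"))
#' @rdname cellCentres
#' @export
setMethod("cellCentres", "RasterGrid", function(x) {
  nr <- nrow(x@values); nc <- ncol(x@values)
  cs <- x@cellsize
  list(x = x@xll + (seq_len(nc) - 0.5) * cs,
       y = x@yll + (nr - seq_len(nr) + 0.5) * cs)
})

#' Convert results to a plain data.frame row
#' @param x a [SummaryStats-class] or [IntervalEstimate-class].
#' @param ... ignored.
#' @return one-row data.frame.
#' @export
setMethod("as.data.frame", "SummaryStats", function(x, ...) {
  data.frame(min = x@min, q25 = x@q25, median = x@median, mean = x@mean,
             q75 = x@q75, max = x@max)
})
#' @rdname as.data.frame-SummaryStats-method
#' @export
setMethod("as.data.frame", "IntervalEstimate", function(x, ...) {
  data.frame(lower = x@lower, median = x@median, upper = x@upper,
             level = x@level)
})

#' @export
setMethod("$", "SummaryStats", function(x, name) slot(x, name))

setMethod("show", "CityModel", function(object) {
  d <- object@data
  cat("CityModel:", nrow(d), "elements, CRS", object@crs, "\n")
  cat("  total area:", format(round(sum(d$area))), "m2;",
      "edible area:", format(round(sum(d$edible_area))), "m2\n")
  tab <- sort(table(d$land_use), decreasing = TRUE)
  cat("  land uses:",
      paste0(names(tab), " (", as.integer(tab), ")", collapse = ", "), "\n")
})

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  cat(class(object), ":", nrow(v), "x", ncol(v), "cells of",
      object@cellsize, "m, CRS", object@crs, "\n")
  fin <- v[is.finite(v)]
  if (length(fin))
    cat("  values:", format(signif(range(fin), 4)[1]), "-",
        format(signif(range(fin), 4)[2]),
        sprintf(" (%d nodata)", sum(!is.finite(v))), "\n")
})

setMethod("show", "NeighbourhoodLayer", function(object) {
  cat("NeighbourhoodLayer:", nrow(object@data), "neighbourhoods, CRS",
      object@crs, "\n")
  print(object@data)
})

setMethod("show", "SummaryStats", function(object) {
  print(round(c(min = object@min, q25 = object@q25, median = object@median,
                mean = object@mean, q75 = object@q75, max = object@max), 4))
})

setMethod("show", "IntervalEstimate", function(object) {
  cat(sprintf("%.0f%% interval: lower %.4g, median %.4g, upper %.4g\n",
              100 * object@level, object@lower, object@median,
              object@upper))
})
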