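# Urban heat island: a diagnostic equation for the maximum air
# temperature difference between the urban canyon and its rural
# surroundings, driven per raster cell by sky view factor and vegetation
# fraction under daily-scale meteorology.

#' Rasterize the vegetation fraction of a city
#'
#' Each cell of the template grid receives the green fraction of the
#' polygon containing its centre: the land use's `pGreen`, overridden by
#' the element-level `edible_area / area` for urban-agriculture (edible)
#' land uses. Cells over no polygon get 0.
#'
#' @param city a [CityModel-class].
#' @param tab attribute table (see [defaultAttributeTable()]).
#' @param template an [SvfGrid-class] (or any [RasterGrid-class]) giving
#'   the grid shape and georeferencing.
#' @return An [SvfGrid-class] of vegetation fractions in `[0, 1]`.
#' @export
rasterizeFveg <- function(city, tab = defaultAttributeTable(),
                          template) {
  stopifnot(is(city, "CityModel"), is(template, "RasterGrid"))
  tab <- validateAttributeTable(tab)
  if (!identical(city@crs, template@crs))
    stop("CRS mismatch between city (", city@crs, ") and raster (",
         template@crs, "); reproject one of them", call. = FALSE)
  cc <- cellCentres(template)
  nr <- length(cc$y); ncol_ <- length(cc$x)
  px <- rep(cc$x, each = nr)          # column-major over (row, col)
  py <- rep(cc$y, times = ncol_)
  fveg <- numeric(length(px))
  d <- city@data
  if (nrow(d)) {
    .requireLandUses(tab, d$land_use, "vegetation fraction")
    rows <- .tableRows(tab, d$land_use)
    val <- ifelse(rows$edible,
                  ifelse(d$area > 0, d$edible_area / d$area, 0),
                  rows$pGreen)
    for (i in seq_len(nrow(d))) {
      bb <- .geomBBox(city@geometry[[i]])
      sel <- which(px >= bb["xmin"] & px <= bb["xmax"] &
                   py >= bb["ymin"] & py <= bb["ymax"])
      if (!length(sel)) next
      inside <- .pointsInGeom(px[sel], py[sel], city@geometry[[i]])
      fveg[sel[inside]] <- val[i]
    }
  }
  m <- matrix(fveg, nrow = nr, ncol = ncol_)
  rasterGrid(m, template@xll, template@yll, template@cellsize,
             crs = template@crs, svf = TRUE)
}

#' Urban heat island indicator
#'
#' Per finite SVF cell `i` the temperature excess is
#' `UHI_i = (2 - SVF_i - Fveg_i) * (Qql * dT^3 / (Cair * Pair * U))^(1/4)`
#' with `dT = Tmax - Tmin` (degrees C) and `U` the wind speed; negative
#' values (possible only through numerical noise) are floored at 0.
#' Nodata SVF cells are excluded everywhere.
#'
#' @param city a [CityModel-class].
#' @param svf an [SvfGrid-class].
#' @param tab attribute table supplying `pGreen` per land use.
#' @param params a [UhiParams-class] (defaults describe a Mediterranean
#'   summer day).
#' @param return_raster return the per-cell grid as a
#'   [RasterGrid-class] instead of a summary.
#' @param verbose return the flat vector of per-cell values instead of a
#'   summary.
#' @return A [SummaryStats-class] of the per-cell values (default), a
#'   [RasterGrid-class] (`return_raster = TRUE`) or a numeric vector
#'   (`verbose = TRUE`), all in degrees C.
#' @examples
#' city <- generateCity(syntheticConfig(seed = 7))
#' svf <- generateSvf(city, cell_size = 20)
#' uhi(city, svf, tab = defaultAttributeTable(impervious = TRUE))
#' @export
uhi <- function(city, svf, tab = defaultAttributeTable(),
                params = uhiParams(), return_raster = FALSE,
                verbose = FALSE) {
  stopifnot(is(city, "CityModel"), is(svf, "SvfGrid"),
            is(params, "UhiParams"))
  validObject(params)
  if (!any(is.finite(svf@values)))
    stop("SVF raster has no finite cells", call. = FALSE)
  fveg <- rasterizeFveg(city, tab, svf)
  vals <- uhiCellValues(svf@values, fveg@values, params)
  if (return_raster)
    return(rasterGrid(vals, svf@xll, svf@yll, svf@cellsize,
                      crs = svf@crs))
  flat <- vals[is.finite(vals)]
  if (verbose) flat else summaryStats(flat)
}

#' Closed-form UHI cell equation
#'
#' Exposed separately so the arithmetic can be checked cell-wise against
#' independent computations.
#'
#' @param svf,fveg numeric (vectors/matrices of equal shape) in `[0, 1]`.
#' @param params a [UhiParams-class].
#' @return numeric of the same shape; `NA` where `svf` is `NA`.
#' @export
uhiCellValues <- function(svf, fveg, params = uhiParams()) {
  dT <- params@Tmax - params@Tmin
  met <- (params@Qql * dT^3 /
            (params@Cair * params@Pair * params@windspeed))^(1 / 4)
  pmax(0, (2 - svf - fveg)) * met
}
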