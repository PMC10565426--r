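# SCS curve-number runoff for a 24-hour design storm, with an initial
# abstraction augmented by rainwater harvested from adjacent taller
# buildings into storage tanks.

#' Potential soil-moisture retention from a curve number
#'
#' Metric SCS form `S = 25400 / CN - 254` (mm).
#'
#' @param CN curve number(s) in `(0, 100]`.
#' @return retention S in mm.
#' @examples
#' potentialRetention(c(50, 98, 100))
#' @export
potentialRetention <- function(CN) {
  if (any(CN <= 0 | CN > 100))
    stop("curve numbers must lie in (0, 100]", call. = FALSE)
  25400 / CN - 254
}

#' Rainwater-harvesting terms per element
#'
#' For each harvest-capable element (per the table's `harvest` flag) the
#' potential harvest `Rh` is the rain fallen on adjacent taller roofs:
#' the summed area of elements within `harvest_dist` metres of its
#' boundary that have strictly more floors and are not urban-agriculture
#' (edible) land uses, times the storm depth (1 mm on 1 m2 = 1 litre).
#' Each catchment element is credited to its nearest harvester only, so
#' no raindrop is counted twice. The storage capacity `Ws` is a uniform
#' draw from `tank_size` (litres per m2) times the element area.
#' Non-harvesting elements get `Rh = Ws = 0`.
#'
#' @param city a [CityModel-class].
#' @param tab attribute table with `harvest` and `edible` flags.
#' @param params a [RunoffParams-class].
#' @return data.frame with columns `Rh` and `Ws` (litres), one row per
#'   element.
#' @export
harvestTerms <- function(city, tab = defaultAttributeTable(),
                         params = runoffParams()) {
  stopifnot(is(city, "CityModel"), is(params, "RunoffParams"))
  tab <- validateAttributeTable(tab)
  d <- city@data
  n <- nrow(d)
  Rh <- numeric(n); Ws <- numeric(n)
  if (n == 0) return(data.frame(Rh = Rh, Ws = Ws))
  .requireLandUses(tab, d$land_use, "rainwater harvesting")
  rows <- .tableRows(tab, d$land_use)
  floors <- d[[params@floors_field]]
  if (is.null(floors))
    stop("floors_field '", params@floors_field,
         "' is not an attribute of the city", call. = FALSE)
  harvesters <- which(rows$harvest)
  # Ws drawn in element order for reproducibility
  if (length(harvesters))
    Ws[harvesters] <- stats::runif(length(harvesters), params@tank_size[1],
                                   params@tank_size[2]) * d$area[harvesters]
  catchments <- which(!rows$edible & floors > 0)
  if (length(harvesters) && length(catchments)) {
    bbs <- lapply(city@geometry, .geomBBox)
    hd <- params@harvest_dist
    for (ci in catchments) {
      best <- NA_integer_; bestd <- Inf
      for (hi in harvesters) {
        if (floors[ci] <= floors[hi]) next
        if (.bboxDist(bbs[[ci]], bbs[[hi]]) > hd) next
        dist <- .geomDist(city@geometry[[ci]], city@geometry[[hi]])
        if (dist <= hd && dist < bestd) { bestd <- dist; best <- hi }
      }
      if (!is.na(best)) Rh[best] <- Rh[best] + params@rain * d$area[ci]
    }
  }
  data.frame(Rh = Rh, Ws = Ws)
}

#' Runoff prevention indicator
#'
#' Per element the curve number is drawn uniformly from the land use's
#' `[CN1, CN2]`, retention is `S = 25400/CN - 254` and the initial
#' abstraction is `Ia = 0.2 S + min(Rh, Ws) / area` (harvested litres
#' over m2 give mm). Runoff is `Q = (P - Ia)^2 / ((P - Ia) + S)` when
#' `P > Ia`, else 0. The city-scale figure is the area-weighted mean of
#' the per-element `Q`.
#'
#' Randomness (curve numbers, tank sizes) uses R's global RNG stream:
#' call `set.seed()` first for reproducible results.
#'
#' @param city a [CityModel-class].
#' @param tab attribute table with `CN1`, `CN2` and the flags.
#' @param params a [RunoffParams-class] (`rain = 85` mm by default).
#' @param verbose return the per-element hydrology table instead of the
#'   city aggregate.
#' @return One-row data.frame with `runoff` (mm), `rainfall` (m3,
#'   `= rain * total area / 1000`) and `rainharvest` (m3); or, when
#'   `verbose = TRUE`, a per-element data.frame with `CN`, `S`, `Rh`,
#'   `Ws`, `Ia` and `Q`.
#' @examples
#' city <- generateCity(syntheticConfig(seed = 7))
#' set.seed(1)
#' runoffPrev(city, tab = defaultAttributeTable(impervious = TRUE))
#' @export
runoffPrev <- function(city, tab = defaultAttributeTable(),
                       params = runoffParams(), verbose = FALSE) {
  stopifnot(is(city, "CityModel"), is(params, "RunoffParams"))
  validObject(params)
  tab <- validateAttributeTable(tab)
  d <- city@data
  P <- params@rain
  if (nrow(d) == 0)
    return(data.frame(runoff = 0, rainfall = 0, rainharvest = 0))
  .requireLandUses(tab, d$land_use, "runoff")
  rows <- .tableRows(tab, d$land_use)
  CN <- stats::runif(nrow(d), rows$CN1, rows$CN2)
  S <- potentialRetention(CN)
  ht <- harvestTerms(city, tab, params)
  harvested <- pmin(ht$Rh, ht$Ws)
  Ia <- 0.2 * S + harvested / d$area
  Q <- ifelse(P <= Ia, 0, (P - Ia)^2 / ((P - Ia) + S))
  if (verbose)
    return(data.frame(id = d$id, CN = CN, S = S, Rh = ht$Rh, Ws = ht$Ws,
                      Ia = Ia, Q = Q))
  total <- sum(d$area)
  data.frame(runoff = sum(Q * d$area) / total,
             rainfall = P * total / 1000,
             rainharvest = sum(harvested) / 1000)
}
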