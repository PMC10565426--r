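# Green-area accessibility (distance from every residence to its closest
# public green area) and green-per-capita equity across neighbourhoods.

# Minimum boundary-to-boundary distance from each geometry in `from` to
# the nearest geometry in `to` (0 when they intersect). Exact pairwise
# computation with bounding-box pruning.
.nearestDistances <- function(fromGeoms, toGeoms) {
  fromBB <- lapply(fromGeoms, .geomBBox)
  toBB <- lapply(toGeoms, .geomBBox)
  vapply(seq_along(fromGeoms), function(i) {
    lower <- vapply(toBB, function(b) .bboxDist(fromBB[[i]], b), numeric(1))
    best <- Inf
    for (j in order(lower)) {
      if (lower[j] >= best) break
      best <- min(best, .geomDist(fromGeoms[[i]], toGeoms[[j]]))
      if (best == 0) break
    }
    best
  }, numeric(1))
}

#' Distance from residences to public green areas
#'
#' Qualifying green areas are the elements whose land use is flagged
#' `public` in the table (or whose land use is listed in `green_cat`) and
#' whose area reaches `min_area`. For every residence the straight-line
#' (Euclidean) boundary-to-boundary distance to the closest qualifying
#' green area is computed; intersecting geometries are at distance 0.
#' The defaults for `min_area` (5000 m2 = 0.5 ha) and `max_dist` (300 m)
#' follow the WHO recommendation that every home have a public green
#' area of at least half a hectare within 300 m.
#'
#' @param city a [CityModel-class].
#' @param tab attribute table with the `public` flag.
#' @param green_cat optional character vector of land uses to use as
#'   green areas instead of the `public` flag.
#' @param residence_col attribute identifying residences (default
#'   `"land_use_verbose"`).
#' @param residences categories of `residence_col` that count as homes.
#' @param min_area smallest green area considered, m2.
#' @param percent_out return the percentage of residences farther than
#'   `max_dist` from their closest green area.
#' @param max_dist threshold for `percent_out`, metres.
#' @param verbose return the raw per-residence distances.
#' @return A [SummaryStats-class] of distances in metres (default), a
#'   percentage in `[0, 100]` (`percent_out = TRUE`) or a numeric vector
#'   (`verbose = TRUE`).
#' @export
greenDistance <- function(city, tab = defaultAttributeTable(),
                          green_cat = NULL,
                          residence_col = "land_use_verbose",
                          residences = "Residence", min_area = 5000,
                          percent_out = FALSE, max_dist = 300,
                          verbose = FALSE) {
  stopifnot(is(city, "CityModel"))
  d <- city@data
  if (!residence_col %in% names(d))
    stop("residence_col '", residence_col,
         "' is not an attribute of the city", call. = FALSE)
  if (is.null(green_cat)) {
    tab <- validateAttributeTable(tab)
    green_cat <- tab$land_use[tab$public]
  }
  greens <- which(d$land_use %in% green_cat & d$area >= min_area)
  homes <- which(d[[residence_col]] %in% residences)
  if (!length(homes))
    stop("no residences found (", residence_col, " in ",
         paste(residences, collapse = ", "), ")", call. = FALSE)
  if (!length(greens))
    stop("no qualifying public green areas (>= ", min_area,
         " m2); distances are undefined", call. = FALSE)
  dist <- .nearestDistances(city@geometry[homes], city@geometry[greens])
  if (percent_out) return(100 * sum(dist > max_dist) / length(dist))
  if (verbose) dist else summaryStats(dist)
}

#' Green area per capita and neighbourhood equity ratio
#'
#' Green elements are those whose land use is flagged `public` (plus the
#' `private`-flagged ones when `private = TRUE`), or an explicit
#' `green_categories` list. In city mode (`inhabitants` given) the total
#' green area divided by the population is returned (m2/person). In
#' neighbourhood mode (`neighbourhoods` given) each green polygon is
#' apportioned to neighbourhoods by geometric intersection, divided by
#' the neighbourhood population, and the max/min ratio across
#' neighbourhoods with at least `min_inh` inhabitants is returned --
#' 1 means perfect spatial equality, larger values less spatial justice.
#'
#' Neighbourhood intersection areas are exact for convex neighbourhood
#' polygons (such as the slabs from [generateNeighbourhoods()]).
#'
#' @param city a [CityModel-class].
#' @param tab attribute table with `public`/`private` flags.
#' @param green_categories optional explicit land-use list.
#' @param inhabitants city population (city mode).
#' @param neighbourhoods a [NeighbourhoodLayer-class] (equity mode).
#' @param private include private green land uses.
#' @param verbose return the per-neighbourhood table instead of the
#'   ratio.
#' @param min_inh exclude neighbourhoods with fewer inhabitants.
#' @return m2/person (city mode); max/min ratio (equity mode); or a
#'   data.frame with `name`, `green_area`, `inhabitants`,
#'   `green_capita` when `verbose = TRUE`.
#' @export
greenCapita <- function(city, tab = defaultAttributeTable(),
                        green_categories = NULL, inhabitants = NULL,
                        neighbourhoods = NULL, private = FALSE,
                        verbose = FALSE, min_inh = 0) {
  stopifnot(is(city, "CityModel"))
  if (is.null(inhabitants) == is.null(neighbourhoods))
    stop("provide exactly one of 'inhabitants' (city mode) or ",
         "'neighbourhoods' (equity mode)", call. = FALSE)
  d <- city@data
  if (is.null(green_categories)) {
    tab <- validateAttributeTable(tab)
    green_categories <- tab$land_use[tab$public |
                                       (private & tab$private)]
  }
  greens <- which(d$land_use %in% green_categories)
  if (!is.null(inhabitants)) {
    if (inhabitants <= 0) stop("inhabitants must be > 0", call. = FALSE)
    return(sum(d$area[greens]) / inhabitants)
  }
  stopifnot(is(neighbourhoods, "NeighbourhoodLayer"))
  nb <- neighbourhoods@data
  garea <- numeric(nrow(nb))
  for (k in seq_len(nrow(nb))) {
    clipRings <- .asGeom(neighbourhoods@geometry[[k]])
    for (g in greens) {
      inter <- sum(vapply(clipRings, function(cl)
        .geomClipArea(city@geometry[[g]], cl), numeric(1)))
      if (inter > 0) {
        # apportion the attribute area by geometric overlap share
        garea[k] <- garea[k] +
          d$area[g] * inter / .geomArea(city@geometry[[g]])
      }
    }
  }
  keep <- which(nb$inhabitants >= min_inh)
  if (!length(keep))
    stop("all neighbourhoods excluded by min_inh = ", min_inh,
         call. = FALSE)
  if (any(nb$inhabitants[keep] <= 0))
    stop("neighbourhood(s) with zero inhabitants included: ",
         paste(nb$name[keep][nb$inhabitants[keep] <= 0], collapse = ", "),
         "; raise min_inh", call. = FALSE)
  gc <- garea[keep] / nb$inhabitants[keep]
  if (verbose)
    return(data.frame(name = nb$name[keep], green_area = garea[keep],
                      inhabitants = nb$inhabitants[keep],
                      green_capita = gc))
  max(gc) / min(gc)
}
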