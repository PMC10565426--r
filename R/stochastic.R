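# Per-element randomized indicators (NO2 sequestration, jobs,
# volunteers, food production) and the shared Monte-Carlo interval
# engine. All draws are uniform within the calibrated ranges and come
# from R's global RNG stream (set.seed() for reproducibility).

#' Monte-Carlo interval for a linear per-area indicator
#'
#' Each iteration computes `sum(areas * k)` with the rate `k` drawn
#' uniformly from `[lo, hi]` -- once per iteration (`mode = "global"`,
#' one shared rate, as for jobs and volunteers) or independently per
#' element (`mode = "element"`, as for yields). `lo`/`hi` may be vectors
#' over elements in element mode. The empirical `(1-interval)/2`, 0.5
#' and `1-(1-interval)/2` quantiles of the iteration totals are
#' returned.
#'
#' @param areas per-element areas, m2.
#' @param lo,hi rate range per m2.
#' @param mode `"global"` or `"element"` draw structure.
#' @param n_iter number of Monte-Carlo iterations (1000 by default).
#' @param interval two-sided coverage level in (0, 1).
#' @param verbose return the `n_iter` totals instead of the interval.
#' @return An [IntervalEstimate-class], or the totals vector when
#'   `verbose = TRUE`. With no elements a degenerate zero interval.
#' @export
mcInterval <- function(areas, lo, hi, mode = c("global", "element"),
                       n_iter = 1000, interval = 0.95, verbose = FALSE) {
  mode <- match.arg(mode)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  n <- length(areas)
  if (n == 0) {
    totals <- rep(0, n_iter)
  } else if (mode == "global") {
    if (length(lo) != 1 || length(hi) != 1)
      stop("global mode needs scalar lo/hi", call. = FALSE)
    totals <- stats::runif(n_iter, lo, hi) * sum(areas)
  } else {
    draws <- matrix(stats::runif(n_iter * n, lo, hi),
                    nrow = n_iter, ncol = n, byrow = TRUE)
    totals <- as.vector(draws %*% areas)
  }
  if (verbose) return(totals)
  .intervalFromDraws(totals, interval)
}

#' Nitrogen dioxide sequestration indicator
#'
#' `sum(a_i * cap_i) / 1000` over all elements, where `a_i` is the
#' effective green area (element area times the land use's `pGreen`,
#' overridden by `edible_area` for urban-agriculture land uses) and
#' `cap_i` is a uniform draw from the land use's sequestration capacity
#' range `[no2_seq1, no2_seq2]` (ug s-1 m-2). One draw per element per
#' call, matching the indicator's single reported figure.
#'
#' @param city a [CityModel-class].
#' @param tab attribute table with `pGreen`, `no2_seq1`, `no2_seq2` and
#'   the `edible` flag.
#' @return total sequestration (equation units, g/s as reported).
#' @export
no2Seq <- function(city, tab = defaultAttributeTable()) {
  stopifnot(is(city, "CityModel"))
  tab <- validateAttributeTable(tab)
  d <- city@data
  if (nrow(d) == 0) return(0)
  eff <- .effectiveGreenArea(city, tab)
  rows <- .tableRows(tab, d$land_use)
  cap <- stats::runif(nrow(d), rows$no2_seq1, rows$no2_seq2)
  sum(eff * cap) / 1000
}

.uaAreas <- function(city, land_uses, area_col) {
  d <- city@data
  sel <- d$land_use %in% land_uses
  if (is.null(area_col)) return(d$area[sel])
  if (!area_col %in% names(d))
    stop("area_col '", area_col, "' is not an attribute of the city",
         call. = FALSE)
  d[[area_col]][sel]
}

#' Jobs created by commercial urban agriculture
#'
#' `sum(a_i * k)` over the commercial urban-agriculture elements
#' (`Commercial garden`, `Hydroponic rooftop` by default), with `a_i`
#' the growing area (`area_col`) and one rate `k` (jobs per m2) drawn
#' per Monte-Carlo iteration from the `jobs` range.
#'
#' @param city a [CityModel-class].
#' @param jobs rate range `c(lo, hi)`, jobs per m2.
#' @param edible land uses counted; defaults to the commercial
#'   urban-agriculture solutions.
#' @param area_col attribute holding the growing area.
#' @param interval two-sided coverage level.
#' @param verbose return the 1000 iteration totals.
#' @param n_iter number of Monte-Carlo iterations.
#' @return An [IntervalEstimate-class] (zero interval when the city has
#'   no commercial urban agriculture), or the totals when `verbose`.
#' @export
edibleJobs <- function(city, jobs = c(0.000163, 0.022), edible = NULL,
                       area_col = "edible_area", interval = 0.95,
                       verbose = FALSE, n_iter = 1000) {
  stopifnot(is(city, "CityModel"))
  if (is.null(edible)) edible <- .COMMERCIAL_UA
  areas <- .uaAreas(city, edible, area_col)
  mcInterval(areas, jobs[1], jobs[2], mode = "global", n_iter = n_iter,
             interval = interval, verbose = verbose)
}

#' Volunteers involved in community urban agriculture
#'
#' As [edibleJobs()] but over the community urban-agriculture land uses
#' (`Community garden`, `Rooftop garden` by default; edible private
#' gardens are for personal use and count for neither indicator) with
#' the `volunteers` rate range.
#'
#' @inheritParams edibleJobs
#' @param volunteers rate range `c(lo, hi)`, volunteers per m2.
#' @return An [IntervalEstimate-class] or the totals when `verbose`.
#' @export
edibleVolunteers <- function(city, volunteers = c(0.00163, 0.22),
                             edible = NULL, area_col = "edible_area",
                             interval = 0.95, verbose = FALSE,
                             n_iter = 1000) {
  stopifnot(is(city, "CityModel"))
  if (is.null(edible)) edible <- .COMMUNITY_UA
  areas <- .uaAreas(city, edible, area_col)
  mcInterval(areas, volunteers[1], volunteers[2], mode = "global",
             n_iter = n_iter, interval = interval, verbose = verbose)
}

#' Food production of urban agriculture
#'
#' `sum(y_i * a_i)` over the urban-agriculture elements, with the yield
#' `y_i` (kg m-2 yr-1) drawn independently per element from its land
#' use's `[food1, food2]` range each Monte-Carlo iteration, and `a_i`
#' the growing area (`area_col`; the full element `area` when
#' `area_col = NULL`).
#'
#' @param city a [CityModel-class].
#' @param tab attribute table supplying the edible land uses and yield
#'   ranges.
#' @param edible_df optional data.frame with columns `land_uses` (or
#'   `land_use`), `food1`, `food2` overriding the table.
#' @param area_col attribute holding the growing area, or `NULL` for the
#'   full element area.
#' @param interval two-sided coverage level.
#' @param verbose return the 1000 iteration totals.
#' @param n_iter number of Monte-Carlo iterations.
#' @return An [IntervalEstimate-class] in kg/yr (zero interval when the
#'   city has no urban agriculture), or the totals when `verbose`.
#' @export
foodProduction <- function(city, tab = defaultAttributeTable(),
                           edible_df = NULL, area_col = "edible_area",
                           interval = 0.95, verbose = FALSE,
                           n_iter = 1000) {
  stopifnot(is(city, "CityModel"))
  if (is.null(edible_df)) {
    tab <- validateAttributeTable(tab)
    edible_df <- tab[tab$edible, c("land_use", "food1", "food2")]
  } else {
    edible_df <- as.data.frame(edible_df)
    if (!"land_use" %in% names(edible_df) &&
        "land_uses" %in% names(edible_df))
      names(edible_df)[names(edible_df) == "land_uses"] <- "land_use"
    stopifnot(all(c("land_use", "food1", "food2") %in% names(edible_df)))
  }
  d <- city@data
  sel <- which(d$land_use %in% edible_df$land_use)
  areas <- if (is.null(area_col)) d$area[sel] else d[[area_col]][sel]
  rows <- edible_df[match(d$land_use[sel], edible_df$land_use), ]
  mcInterval(areas, rows$food1, rows$food2, mode = "element",
             n_iter = n_iter, interval = interval, verbose = verbose)
}
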