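# Scenario generator: converts a configurable share of private gardens,
# ground plots and rooftops into the five urban-agriculture solution
# types (edible private garden, community/commercial garden, rooftop
# garden, hydroponic rooftop).

# Half-away-from-zero rounding (R's round() is half-even).
.roundHalf <- function(x) sign(x) * floor(abs(x) + 0.5)

# Select elements of one location class. Assumed target counts are based
# on ALL candidates; eligibility (min_area on area_field) caps them, with
# the informative message comparing both counts. Selection is the head of
# one uniform random permutation of the eligible pool, except commercial
# conversions which take the largest eligible elements.
.convertClass <- function(d, afield, sources, min_area, p, pCommercial,
                          commercial_use, community_use, noun, min_name) {
  cand <- which(d$land_use %in% sources)
  msgs <- character(0)
  if (!length(cand)) {
    if (p > 0)
      msgs <- paste0("No elements with land use ",
                     paste(sQuote(sources), collapse = ", "),
                     " found; nothing converted")
    return(list(commercial = integer(0), community = integer(0),
                messages = msgs))
  }
  n <- .roundHalf(p * length(cand))
  elig <- cand[d[[afield]][cand] >= min_area]
  if (length(elig) < n) {
    msgs <- sprintf("Only %d %s out of %d assumed satisfy the '%s'",
                    length(elig), noun, n, min_name)
    n <- length(elig)
  }
  if (n == 0)
    return(list(commercial = integer(0), community = integer(0),
                messages = msgs))
  n_com <- min(n, .roundHalf(pCommercial * n))
  com <- if (n_com > 0)
    elig[order(d[[afield]][elig], decreasing = TRUE)][seq_len(n_com)]
  else integer(0)
  rest <- setdiff(elig, com)
  comm <- if (n - n_com > 0) {
    perm <- if (length(rest) > 1) sample(rest) else rest
    perm[seq_len(n - n_com)]
  } else integer(0)
  list(commercial = com, community = comm, messages = msgs)
}

#' Build an urban-agriculture scenario
#'
#' Converts a proportion of the city's private gardens, vacant ground
#' plots and rooftops into urban-agriculture solutions. The assumed
#' number of conversions per class is `round(p * candidates)` over all
#' candidate elements; only candidates whose `area_field` reaches the
#' class minimum area are eligible, and when eligibility falls short all
#' eligible elements are converted and an informative message is emitted
#' (suppressed by `quiet`). Locations are drawn uniformly at random
#' without replacement -- except commercial conversions, which occupy the
#' largest eligible elements. Ground conversions with commercial purpose
#' become `"Commercial garden"`, the rest `"Community garden"`; rooftop
#' conversions become `"Hydroponic rooftop"` (commercial) or
#' `"Rooftop garden"`; private gardens always become
#' `"Edible private garden"`. Every converted element receives
#' `edible_area = u * area_field` with `u` drawn uniformly from the class
#' range; all other attributes (including `floors`) are untouched.
#'
#' Randomness uses R's global RNG stream: call `set.seed()` first for a
#' reproducible scenario.
#'
#' @param city a [CityModel-class].
#' @param params a [ScenarioParams-class]; see [scenarioParams()] for the
#'   defaults.
#' @param quiet suppress the eligibility messages (defaults to the
#'   `quiet` slot of `params`).
#' @return The scenario [CityModel-class] (same element count, ids and
#'   geometry as the input). The messages emitted, if any, are attached
#'   as `attr(result, "messages")`.
#' @examples
#' city <- generateCity(syntheticConfig(seed = 7))
#' set.seed(1)
#' sc <- setScenario(city, scenarioParams(pCommercial = 0.5))
#' table(elements(sc)$land_use)
#' @export
setScenario <- function(city, params = scenarioParams(),
                        quiet = params@quiet) {
  stopifnot(is(city, "CityModel"), is(params, "ScenarioParams"))
  validObject(params)
  d <- city@data
  afield <- params@area_field
  if (!afield %in% names(d))
    stop("area_field '", afield, "' is not an attribute of the city",
         call. = FALSE)
  msgs <- character(0)

  gard <- .convertClass(d, afield, params@private_gardens_from,
                        params@min_area_garden, params@pGardens,
                        pCommercial = 0, commercial_use = NA,
                        community_use = NA, noun = "private gardens",
                        min_name = "min_area_garden")
  vac <- .convertClass(d, afield, params@vacant_from,
                       params@min_area_vacant, params@pVacant,
                       params@pCommercial, "Commercial garden",
                       "Community garden", noun = "vacant plots",
                       min_name = "min_area_vacant")
  roof <- .convertClass(d, afield, params@rooftop_from,
                        params@min_area_rooftop, params@pRooftop,
                        params@pCommercial, "Hydroponic rooftop",
                        "Rooftop garden", noun = "rooftops",
                        min_name = "min_area_rooftop")
  msgs <- c(gard$messages, vac$messages, roof$messages)

  assign_use <- function(d, idx, use, range) {
    if (!length(idx)) return(d)
    d$land_use[idx] <- use
    u <- stats::runif(length(idx), range[1], range[2])
    d$edible_area[idx] <- u * d[[afield]][idx]
    d
  }
  d <- assign_use(d, c(gard$commercial, gard$community),
                  "Edible private garden", params@edible_area_garden)
  d <- assign_use(d, vac$commercial, "Commercial garden",
                  params@edible_area_vacant)
  d <- assign_use(d, vac$community, "Community garden",
                  params@edible_area_vacant)
  d <- assign_use(d, roof$commercial, "Hydroponic rooftop",
                  params@edible_area_rooftop)
  d <- assign_use(d, roof$community, "Rooftop garden",
                  params@edible_area_rooftop)

  if (!quiet) for (m in msgs) message(m)
  out <- new("CityModel", data = d, geometry = city@geometry,
             crs = city@crs)
  attr(out, "messages") <- msgs
  out
}
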