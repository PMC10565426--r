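# Scenario-comparison report: builds each scenario from the base city
# and runs the eight indicators on every one, with a master seed split
# into named substreams so adding an indicator never perturbs
# another's draws.

.SUBSTREAMS <- c(scenario = 1L, runoff = 2L, no2 = 3L, jobs = 4L,
                 volunteers = 5L, food = 6L)

# Deterministic 32-bit substream seed from (master seed, scenario index,
# purpose name).
.subSeed <- function(seed, scen_idx, purpose) {
  base <- (as.numeric(seed) %% 2147483647)
  (base * 31 + scen_idx * 101 + .SUBSTREAMS[[purpose]] * 7919) %%
    2147483647
}

.withContext <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("scenario '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Scenario-comparison report
#'
#' Builds every scenario in `scenario_specs` from the base city and runs
#' the eight indicators on each (and on the base), returning tidy
#' per-scenario tables: urban-agriculture element counts and surfaces,
#' the UHI six-number summary, the runoff / rainfall / rainwater-harvest
#' triplet, the NO2 sequestration total, jobs and volunteers intervals,
#' the green-accessibility summary, green per capita, and the food
#' production interval. A master `seed` is split into named substreams
#' (scenario, runoff, no2, jobs, volunteers, food) per scenario, so two
#' runs with the same seed are identical and indicators do not perturb
#' each other's draws.
#'
#' @param city the base [CityModel-class].
#' @param svf an [SvfGrid-class] covering the city.
#' @param neighbourhoods optional [NeighbourhoodLayer-class]; when
#'   supplied the green-per-capita equity ratio is included.
#' @param scenario_specs named list of [ScenarioParams-class]; a `NULL`
#'   entry stands for the unchanged base city.
#' @param seed master integer seed.
#' @param tab attribute table used by every indicator
#'   ([defaultAttributeTable()] with impervious rows by default, so
#'   whole cities run without extra rows).
#' @param gd_min_area minimum green area (m2) for the accessibility
#'   indicator.
#' @param min_inh neighbourhood population threshold for green per
#'   capita.
#' @param out_dir optional directory; when given, every table is written
#'   as CSV plus a combined JSON bundle `report.json`.
#' @return Invisibly-printable list of data.frames: `ua`, `uhi`,
#'   `runoff`, `no2`, `jobs`, `volunteers`, `green_distance`,
#'   `green_capita` (when neighbourhoods are given), `food`, and
#'   `messages` (the scenario-builder eligibility messages).
#' @examples
#' city <- generateCity(syntheticConfig(seed = 7))
#' svf <- generateSvf(city)
#' rep <- runReport(city, svf,
#'                  scenario_specs = list(base = NULL,
#'                                        full = scenarioParams()),
#'                  seed = 42)
#' rep$runoff
#' @export
runReport <- function(city, svf, neighbourhoods = NULL,
                      scenario_specs = list(base = NULL),
                      seed = 1L,
                      tab = defaultAttributeTable(impervious = TRUE),
                      gd_min_area = 5000, min_inh = 0, out_dir = NULL) {
  stopifnot(is(city, "CityModel"), is(svf, "SvfGrid"),
            length(scenario_specs) >= 1)
  tab <- validateAttributeTable(tab)
  nm <- names(scenario_specs)
  if (is.null(nm) || any(nm == ""))
    nm <- names(scenario_specs) <-
      paste0("s", seq_along(scenario_specs) - 1)

  scenarios <- list()
  messages <- data.frame(scenario = character(0), message = character(0))
  for (k in seq_along(scenario_specs)) {
    spec <- scenario_specs[[k]]
    if (is.null(spec)) {
      scenarios[[nm[k]]] <- city
    } else {
      sc <- .withContext(nm[k], .withSeed(.subSeed(seed, k, "scenario"),
                                          setScenario(city, spec,
                                                      quiet = TRUE)))
      msgs <- attr(sc, "messages")
      if (length(msgs))
        messages <- rbind(messages,
                          data.frame(scenario = nm[k], message = msgs))
      scenarios[[nm[k]]] <- sc
    }
  }

  row_ua <- function(sc) {
    d <- sc@data
    do.call(rbind, lapply(.UA_LAND_USES, function(u) {
      sel <- d$land_use == u
      data.frame(land_use = u, n = sum(sel), area = sum(d$area[sel]),
                 edible_area = sum(d$edible_area[sel]))
    }))
  }

  bind_named <- function(rows) {
    out <- do.call(rbind, rows)
    out <- cbind(scenario = rep(names(rows),
                                vapply(rows, nrow, 0L)), out)
    rownames(out) <- NULL
    out
  }

  ua <- bind_named(lapply(scenarios, row_ua))
  uhi_tab <- bind_named(lapply(nm, function(s) .withContext(s,
    as.data.frame(uhi(scenarios[[s]], svf, tab)))) |>
    stats::setNames(nm))
  runoff_tab <- bind_named(stats::setNames(lapply(seq_along(nm),
    function(k) .withContext(nm[k],
      .withSeed(.subSeed(seed, k, "runoff"),
                runoffPrev(scenarios[[k]], tab)))), nm))
  no2_tab <- bind_named(stats::setNames(lapply(seq_along(nm),
    function(k) .withContext(nm[k], data.frame(
      no2_gs = .withSeed(.subSeed(seed, k, "no2"),
                         no2Seq(scenarios[[k]], tab))))), nm))
  jobs_tab <- bind_named(stats::setNames(lapply(seq_along(nm),
    function(k) .withContext(nm[k],
      as.data.frame(.withSeed(.subSeed(seed, k, "jobs"),
                              edibleJobs(scenarios[[k]]))))), nm))
  vol_tab <- bind_named(stats::setNames(lapply(seq_along(nm),
    function(k) .withContext(nm[k],
      as.data.frame(.withSeed(.subSeed(seed, k, "volunteers"),
                              edibleVolunteers(scenarios[[k]]))))), nm))
  gd_tab <- bind_named(stats::setNames(lapply(nm, function(s)
    .withContext(s, as.data.frame(
      greenDistance(scenarios[[s]], tab, min_area = gd_min_area)))),
    nm))
  food_tab <- bind_named(stats::setNames(lapply(seq_along(nm),
    function(k) .withContext(nm[k],
      as.data.frame(.withSeed(.subSeed(seed, k, "food"),
                              foodProduction(scenarios[[k]], tab))))),
    nm))

  out <- list(ua = ua, uhi = uhi_tab, runoff = runoff_tab,
              no2 = no2_tab, jobs = jobs_tab, volunteers = vol_tab,
              green_distance = gd_tab, food = food_tab,
              messages = messages)
  if (!is.null(neighbourhoods)) {
    out$green_capita <- bind_named(stats::setNames(lapply(nm,
      function(s) .withContext(s, data.frame(
        ratio = greenCapita(scenarios[[s]], tab,
                            neighbourhoods = neighbourhoods,
                            private = TRUE, min_inh = min_inh)))), nm))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (name in names(out))
      utils::write.csv(out[[name]],
                       file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(out, file.path(out_dir, "report.json"),
                         dataframe = "rows", digits = NA, pretty = TRUE)
  }
  out
}
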