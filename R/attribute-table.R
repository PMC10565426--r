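# Per-land-use parameter table: green fraction, NO2 sequestration
# capacity range (ug s-1 m-2), yield range (kg m-2 yr-1), SCS curve
# number range, and the four logical flags the indicators use to select
# element classes (edible / public green / private green / rainwater
# harvesting).

.UA_LAND_USES <- c("Edible private garden", "Community garden",
                   "Commercial garden", "Rooftop garden",
                   "Hydroponic rooftop")
.COMMERCIAL_UA <- c("Commercial garden", "Hydroponic rooftop")
.COMMUNITY_UA <- c("Community garden", "Rooftop garden")

#' Default land-use attribute table
#'
#' Returns the reference table of green typologies: for each land use the
#' proportion of green surface (`pGreen`, overridden by
#' `edible_area/area` for urban-agriculture solutions), the low/high NO2
#' sequestration capacity (`no2_seq1`, `no2_seq2`, ug s-1 m-2), the
#' low/high food yield (`food1`, `food2`, kg m-2 yr-1), the low/high SCS
#' curve number (`CN1`, `CN2`) and the logical flags `edible`, `public`,
#' `private`, `harvest`.
#'
#' @param impervious logical; when `TRUE`, append rows for the impervious
#'   built land uses (`Rooftop`, `Streets`, `Building`: no green, curve
#'   number 98) so a whole city can be run through the indicators without
#'   user-supplied rows.
#' @return data.frame keyed by `land_use`.
#' @seealso [readAttributeTable()], [writeAttributeTable()]
#' @export
defaultAttributeTable <- function(impervious = FALSE) {
  tab <- data.frame(
    land_use = c("Edible private garden", "Community garden",
                 "Commercial garden", "Rooftop garden",
                 "Hydroponic rooftop", "Arable land", "Normal garden",
                 "Permanent crops", "Vacant", "Grass", "Mulcher",
                 "Raised bed", "Trees", "Vegetated pergola"),
    pGreen   = c(0.6, 1.0, 1.0, 1.0, 1.0, 0.6, 0.6, 0.6, 1.0, 1.0, 1.0,
                 1.0, 1.0, 1.0),
    no2_seq1 = c(0.07, 0.07, 0.07, 0.07, 0.07, 0.00, 0.07, 0.09, 0.07,
                 0.07, 0.00, 0.07, 0.11, 0.07),
    no2_seq2 = c(0.09, 0.09, 0.09, 0.07, 0.07, 0.07, 0.07, 0.09, 0.09,
                 0.07, 0.00, 0.07, 0.11, 0.07),
    food1    = c(0.2, 0.2, 4.0, 0.2, 9.0, 4.0, 1.0, 4.0, 1.0, 1.0, 1.0,
                 1.0, 1.0, 1.0),
    food2    = c(6.6, 2.2, 6.6, 2.2, 19.0, 6.6, 1.0, 6.6, 1.0, 1.0, 1.0,
                 1.0, 1.0, 1.0),
    CN1      = c(85, 85, 85, 67, 98, 85, 74, 65, 74, 74, 88, 67, 70, 98),
    CN2      = c(88, 88, 85, 88, 98, 88, 86, 77, 87, 86, 88, 88, 77, 98),
    stringsAsFactors = FALSE)
  tab$edible <- tab$land_use %in% .UA_LAND_USES
  tab$public <- tab$land_use %in% c("Community garden", "Arable land",
                                    "Permanent crops", "Grass", "Trees")
  tab$private <- tab$land_use %in% c("Edible private garden",
                                     "Normal garden")
  tab$harvest <- tab$edible | tab$land_use == "Raised bed"
  if (impervious) {
    imp <- data.frame(
      land_use = c("Rooftop", "Streets", "Building"),
      pGreen = 0, no2_seq1 = 0, no2_seq2 = 0, food1 = 0, food2 = 0,
      CN1 = 98, CN2 = 98, edible = FALSE, public = FALSE,
      private = FALSE, harvest = FALSE, stringsAsFactors = FALSE)
    tab <- rbind(tab, imp)
  }
  validateAttributeTable(tab)
}

#' Validate a land-use attribute table
#'
#' Checks column presence, key uniqueness and the range invariants
#' (`no2_seq1 <= no2_seq2`, `food1 <= food2`, `CN1 <= CN2`,
#' `0 < CN <= 100`, `0 <= pGreen <= 1`).
#'
#' @param tab data.frame as returned by [defaultAttributeTable()]; a
#'   `land_uses` key column is accepted and renamed to `land_use`.
#' @return the validated (possibly renamed) data.frame, invisibly usable.
#' @export
validateAttributeTable <- function(tab) {
  tab <- as.data.frame(tab)
  if (!"land_use" %in% names(tab) && "land_uses" %in% names(tab))
    names(tab)[names(tab) == "land_uses"] <- "land_use"
  need <- c("land_use", "pGreen", "no2_seq1", "no2_seq2", "food1",
            "food2", "CN1", "CN2")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("attribute table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (fl in c("edible", "public", "private", "harvest"))
    if (!fl %in% names(tab)) tab[[fl]] <- FALSE
  if (anyDuplicated(tab$land_use))
    stop("attribute table land_use keys must be unique", call. = FALSE)
  ok <- tab$no2_seq1 <= tab$no2_seq2 & tab$food1 <= tab$food2 &
    tab$CN1 <= tab$CN2 & tab$CN1 > 0 & tab$CN2 <= 100 &
    tab$pGreen >= 0 & tab$pGreen <= 1
  if (!all(ok))
    stop("attribute table range invariants violated for: ",
         paste(tab$land_use[!ok], collapse = ", "), call. = FALSE)
  rownames(tab) <- NULL
  tab
}

#' Read / write an attribute table as CSV
#'
#' Plain CSV with the [defaultAttributeTable()] columns (flag columns
#' `edible`, `public`, `private`, `harvest` included).
#'
#' @param path file path.
#' @return `readAttributeTable` returns the validated data.frame;
#'   `writeAttributeTable` returns `path` invisibly.
#' @export
readAttributeTable <- function(path) {
  validateAttributeTable(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname readAttributeTable
#' @param tab data.frame to write.
#' @export
writeAttributeTable <- function(tab, path) {
  utils::write.csv(validateAttributeTable(tab), path, row.names = FALSE)
  invisible(path)
}

# Error (listing the categories) when city land uses are absent from the
# table -- silent zeros would hide data mistakes.
.requireLandUses <- function(tab, uses, what = "indicator") {
  unknown <- setdiff(unique(uses), tab$land_use)
  if (length(unknown))
    stop("land use(s) missing from the attribute table for ", what, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# Row lookup by land use, preserving element order.
.tableRows <- function(tab, uses) {
  tab[match(uses, tab$land_use), , drop = FALSE]
}

# Effective green area per element: area * pGreen, overridden by
# edible_area for urban-agriculture (edible-flagged) land uses.
.effectiveGreenArea <- function(city, tab) {
  d <- city@data
  .requireLandUses(tab, d$land_use, "green fraction")
  rows <- .tableRows(tab, d$land_use)
  ifelse(rows$edible, d$edible_area, d$area * rows$pGreen)
}
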