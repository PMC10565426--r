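# Domain types, the default attribute table, file round-trips and the
# six-number summary.

test_that("default attribute table reproduces the reference CSV", {
  ref <- read.csv(test_path("table2.csv"), stringsAsFactors = FALSE)
  tab <- defaultAttributeTable()
  expect_equal(nrow(tab), 14)
  expect_equal(tab[, names(ref)], ref)
  # spot values
  hydro <- tab[tab$land_use == "Hydroponic rooftop", ]
  expect_equal(c(hydro$food1, hydro$food2, hydro$CN1, hydro$CN2),
               c(9.0, 19.0, 98, 98))
  trees <- tab[tab$land_use == "Trees", ]
  expect_equal(c(trees$no2_seq1, trees$no2_seq2, trees$pGreen),
               c(0.11, 0.11, 1.0))
  epg <- tab[tab$land_use == "Edible private garden", ]
  expect_equal(c(epg$pGreen, epg$CN1, epg$CN2), c(0.6, 85, 88))
})

test_that("attribute flags select the urban-agriculture classes", {
  tab <- defaultAttributeTable()
  expect_setequal(tab$land_use[tab$edible],
                  c("Edible private garden", "Community garden",
                    "Commercial garden", "Rooftop garden",
                    "Hydroponic rooftop"))
  expect_true(all(tab$harvest[tab$edible]))
  expect_true(tab$harvest[tab$land_use == "Raised bed"])
  expect_false(any(tab$public & tab$private))
  # extended table covers built land and keeps the 14 green rows intact
  full <- defaultAttributeTable(impervious = TRUE)
  expect_true(all(c("Rooftop", "Streets") %in% full$land_use))
  expect_equal(full[1:14, ], tab)
})

test_that("attribute table validation enforces range invariants", {
  tab <- defaultAttributeTable()
  bad <- tab; bad$CN1[1] <- 101
  expect_error(validateAttributeTable(bad), "invariant")
  bad <- tab; bad$food2[2] <- 0.1
  expect_error(validateAttributeTable(bad), "invariant")
  bad <- rbind(tab, tab[1, ])
  expect_error(validateAttributeTable(bad), "unique")
  # a 'land_uses' key column is accepted
  renamed <- tab; names(renamed)[1] <- "land_uses"
  expect_equal(validateAttributeTable(renamed), tab)
})

test_that("cityModel fills defaults and enforces invariants", {
  city <- mixedFixture()
  expect_equal(nElements(city), 12)
  d <- elements(city)
  expect_equal(d$flat_area, d$area)          # filled with area
  expect_equal(d$area, rep(10000, 12))       # recomputed from geometry
  expect_equal(geomAreas(city), d$area)
  expect_error(cityModel(data.frame(floors = 0, area = 1),
                         list(urbanECS:::.rectRing(0, 0, 1, 1))),
               "land_use")
  # inconsistent declared area warns but keeps the attribute
  expect_warning(
    rectCity(data.frame(x = 0, y = 0, w = 100, h = 100,
                        land_use = "Grass", floors = 0, area = 5000)),
    "5%")
  expect_error(cityModel(data.frame(land_use = "Grass", floors = 0),
                         list(urbanECS:::.rectRing(0, 0, 1, 1)),
                         crs = "EPSG:4326"),
               "geographic")
})

test_that("city GeoJSON round-trip preserves attributes and geometry", {
  city <- mixedFixture()
  path <- withr::local_tempfile(fileext = ".geojson")
  writeCity(city, path)
  back <- readCity(path)
  expect_equal(elements(back), elements(city))
  expect_equal(crsName(back), crsName(city))
  for (i in seq_len(nElements(city)))
    expect_equal(geometries(back)[[i]], geometries(city)[[i]],
                 tolerance = 1e-9)
  # overwrite succeeds and fully replaces content
  writeCity(back, path)
  expect_equal(nElements(readCity(path)), 12)
})

test_that("readCity reports missing mandatory columns by name", {
  city <- mixedFixture()
  path <- withr::local_tempfile(fileext = ".geojson")
  writeCity(city, path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  doc$features <- lapply(doc$features, function(f) {
    f$properties$land_use <- NULL
    f
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(readCity(path), "land_use")
})

test_that("empty collections round-trip", {
  empty <- cityModel(
    data.frame(land_use = character(0), floors = numeric(0),
               area = numeric(0)), list())
  path <- withr::local_tempfile(fileext = ".geojson")
  writeCity(empty, path)
  expect_equal(nElements(readCity(path)), 0)
})

test_that("neighbourhood GeoJSON round-trip preserves names and counts", {
  city <- mixedFixture()
  nb <- generateNeighbourhoods(city, 3, c(100, 200, 300))
  path <- withr::local_tempfile(fileext = ".geojson")
  writeNeighbourhoods(nb, path)
  back <- readNeighbourhoods(path)
  expect_equal(elements(back), elements(nb))
  expect_error(generateNeighbourhoods(city, 3, c(1, 2)), "length")
})

test_that("ASCII grid raster round-trips with nodata preserved", {
  m <- matrix(runif(30), nrow = 5)
  m[2, 3] <- NA
  g <- rasterGrid(m, xll = 100, yll = 200, cellsize = 10, svf = TRUE)
  path <- withr::local_tempfile(fileext = ".asc")
  writeRasterGrid(g, path)
  back <- readSvf(path)
  expect_equal(gridValues(back), gridValues(g), tolerance = 1e-6)
  expect_true(is.na(gridValues(back)[2, 3]))
  expect_equal(back@xll, 100)
  expect_equal(back@cellsize, 10)
})

test_that("readSvf rejects rasters that are not sky view factors", {
  m <- matrix(runif(100, 0, 40), nrow = 10)   # e.g. a temperature grid
  path <- withr::local_tempfile(fileext = ".asc")
  writeRasterGrid(rasterGrid(m), path)
  expect_error(readSvf(path), "outside \\[0, 1\\]")
  # truncated file -> format error
  g <- rasterGrid(matrix(0.8, 5, 5), svf = TRUE)
  writeRasterGrid(g, path)
  lines <- readLines(path)
  writeLines(lines[1:8], path)
  expect_error(readSvf(path), "cells")
})

test_that("constant SVF grid reads back as constant", {
  g <- rasterGrid(matrix(0.8, 50, 50), svf = TRUE)
  path <- withr::local_tempfile(fileext = ".asc")
  writeRasterGrid(g, path)
  expect_equal(unique(as.vector(gridValues(readSvf(path)))), 0.8)
})

test_that("summaryStats matches a sorting-based quantile oracle", {
  s <- summaryStats(c(5, 5, 5))
  expect_equal(c(s$min, s$median, s$mean, s$max), c(5, 5, 5, 5))
  s <- summaryStats(c(1, 2, 3, 4))
  expect_equal(c(s$min, s$q25, s$median, s$mean, s$q75, s$max),
               c(1, 1.75, 2.5, 2.5, 3.25, 4))
  expect_error(summaryStats(numeric(0)), "empty")

  # independent type-7 oracle: linear interpolation on sorted values
  oracle_q <- function(x, p) {
    x <- sort(x); n <- length(x)
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  set.seed(42)
  for (rep in 1:100) {
    v <- stats::rnorm(sample(2:40, 1))
    s <- summaryStats(v)
    expect_equal(s$q25, oracle_q(v, 0.25))
    expect_equal(s$median, oracle_q(v, 0.5))
    expect_equal(s$q75, oracle_q(v, 0.75))
    expect_equal(s$mean, sum(v) / length(v))
  }
  # distributional sanity on uniform draws
  set.seed(7)
  u <- stats::runif(1000)
  s <- summaryStats(u)
  expect_equal(c(s$min, s$q25, s$median, s$mean, s$q75, s$max),
               c(0, 0.25, 0.5, 0.5, 0.75, 1), tolerance = 0.05)
})
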