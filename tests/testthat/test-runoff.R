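# SCS curve-number runoff, rainwater harvesting and the modified initial
# abstraction.

test_that("potential retention follows the metric SCS identity", {
  expect_equal(potentialRetention(100), 0)
  expect_equal(potentialRetention(50), 254)
  expect_equal(potentialRetention(98), 25400 / 98 - 254)
  expect_equal(potentialRetention(98), 5.184, tolerance = 1e-3)
  expect_error(potentialRetention(0), "curve numbers")
  expect_error(potentialRetention(101), "curve numbers")
})

# independent SCS oracle for degenerate CN ranges and no harvesting
scsOracle <- function(CN, P) {
  S <- 25400 / CN - 254
  Ia <- 0.2 * S
  if (P <= Ia) 0 else (P - Ia)^2 / ((P - Ia) + S)
}

oneElementCity <- function(land_use = "Grass", w = 100, h = 100,
                           floors = 0) {
  rectCity(data.frame(x = 0, y = 0, w = w, h = h, land_use = land_use,
                      land_use_verbose = "E", floors = floors,
                      stringsAsFactors = FALSE))
}

degenerateTable <- function(CN) {
  tab <- defaultAttributeTable()
  tab$CN1 <- tab$CN2 <- CN
  tab
}

test_that("runoffPrev equals the SCS closed form for degenerate ranges", {
  set.seed(41)
  city <- oneElementCity()
  for (rep in 1:50) {
    CN <- stats::runif(1, 30, 100)
    P <- stats::runif(1, 0, 200)
    res <- runoffPrev(city, degenerateTable(CN),
                      runoffParams(rain = P, tank_size = c(0, 0)))
    expect_equal(res$runoff, scsOracle(CN, P), tolerance = 1e-9)
    expect_equal(res$rainfall, P * 10000 / 1000)
    expect_equal(res$rainharvest, 0)
  }
  # the worked single-element case: CN 98, P 85
  res <- runoffPrev(city, degenerateTable(98),
                    runoffParams(rain = 85, tank_size = c(0, 0)))
  S <- 25400 / 98 - 254
  expect_equal(res$runoff, (85 - 0.2 * S)^2 / ((85 - 0.2 * S) + S))
  expect_equal(res$runoff, 79.2, tolerance = 0.05)
})

test_that("a zero-rain event yields zero everywhere", {
  set.seed(42)
  res <- runoffPrev(mixedFixture(), fullTable(),
                    runoffParams(rain = 0))
  expect_equal(unlist(res), c(runoff = 0, rainfall = 0, rainharvest = 0))
})

test_that("harvest terms credit adjacent taller roofs to the nearest garden", {
  # community garden (floors 0) touching one 3-floor 200 m2 building
  city <- rectCity(data.frame(
    x = c(0, 20), y = 0, w = c(20, 20), h = c(20, 10),
    land_use = c("Community garden", "Rooftop"),
    land_use_verbose = c("CG", "Residence"), floors = c(0, 3),
    stringsAsFactors = FALSE))
  set.seed(43)
  ht <- harvestTerms(city, fullTable(), runoffParams(rain = 85))
  expect_equal(ht$Rh, c(85 * 200, 0))      # 17,000 litres
  expect_equal(ht$Ws[2], 0)                # buildings have no tanks

  # isolated garden: no catchment within harvest_dist
  far <- rectCity(data.frame(
    x = c(0, 100), y = 0, w = c(20, 20), h = c(20, 10),
    land_use = c("Community garden", "Rooftop"),
    land_use_verbose = c("CG", "Residence"), floors = c(0, 3),
    stringsAsFactors = FALSE))
  ht <- harvestTerms(far, fullTable(), runoffParams(rain = 85))
  expect_equal(ht$Rh, c(0, 0))

  # same-height neighbours are not catchments ("strictly higher")
  flat <- rectCity(data.frame(
    x = c(0, 20), y = 0, w = 20, h = 20,
    land_use = c("Community garden", "Rooftop"),
    land_use_verbose = c("CG", "Residence"), floors = c(0, 0),
    stringsAsFactors = FALSE))
  ht <- harvestTerms(flat, fullTable(), runoffParams(rain = 85))
  expect_equal(ht$Rh, c(0, 0))
})

test_that("each catchment is credited once, to its nearest harvester", {
  # two gardens, one building nearer to the first
  city <- rectCity(data.frame(
    x = c(0, 50, 24), y = c(0, 0, 0), w = c(20, 20, 20),
    h = c(20, 20, 10),
    land_use = c("Community garden", "Community garden", "Rooftop"),
    land_use_verbose = c("A", "B", "R"), floors = c(0, 0, 4),
    stringsAsFactors = FALSE))
  set.seed(44)
  ht <- harvestTerms(city, fullTable(), runoffParams(rain = 10))
  expect_equal(ht$Rh, c(10 * 200, 0, 0))
  expect_lte(sum(ht$Rh) / 10, 200)   # total catchment never double-counted
})

test_that("zero tank size reduces to the unmodified SCS model", {
  city <- generateCity(syntheticConfig(seed = 6))
  tab <- fullTable()
  tab$CN1 <- tab$CN2
  set.seed(45)
  res <- runoffPrev(city, tab, runoffParams(tank_size = c(0, 0)))
  # brute-force unmodified SCS on the same deterministic curve numbers
  d <- elements(city)
  CN <- tab$CN2[match(d$land_use, tab$land_use)]
  Q <- vapply(CN, scsOracle, numeric(1), P = 85)
  expect_equal(res$runoff, sum(Q * d$area) / sum(d$area),
               tolerance = 1e-12)
})

test_that("runoff is bounded by rainfall and monotone in curve number", {
  city <- generateCity(syntheticConfig(seed = 8))
  tab <- fullTable()
  for (seed in 1:5) {
    set.seed(seed)
    res <- runoffPrev(city, tab)
    expect_gte(res$runoff, 0)
    expect_lte(res$runoff, 85)
  }
  # raising every (deterministic) CN never decreases runoff
  lowTab <- fullTable(); lowTab$CN2 <- lowTab$CN1
  highTab <- fullTable(); highTab$CN1 <- highTab$CN2
  set.seed(46)
  qlow <- runoffPrev(city, lowTab, runoffParams(tank_size = c(0, 0)))
  set.seed(46)
  qhigh <- runoffPrev(city, highTab, runoffParams(tank_size = c(0, 0)))
  expect_gte(qhigh$runoff, qlow$runoff)
})

test_that("harvest reduces runoff and respects capacity bounds", {
  city <- generateCity(syntheticConfig(seed = 9))
  tab <- fullTable()
  set.seed(47)
  with_tanks <- runoffPrev(city, tab, runoffParams(tank_size = c(45, 45)))
  set.seed(47)
  without <- runoffPrev(city, tab, runoffParams(tank_size = c(0, 0)))
  expect_lte(with_tanks$runoff, without$runoff)
  expect_gte(with_tanks$rainharvest, 0)
  # rainharvest cannot exceed total tank capacity
  d <- elements(city)
  rows <- tab[match(d$land_use, tab$land_use), ]
  expect_lte(with_tanks$rainharvest, sum(45 * d$area[rows$harvest]) / 1000)
})

test_that("missing land uses are reported by name", {
  city <- mixedFixture()
  expect_error(runoffPrev(city, defaultAttributeTable()), "Rooftop")
})
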