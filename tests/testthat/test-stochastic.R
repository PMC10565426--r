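# Monte-Carlo engine and the four randomized indicators.

test_that("degenerate rate ranges give exact closed-form intervals", {
  set.seed(51)
  est <- mcInterval(c(100, 200, 50), 0.4, 0.4, mode = "global")
  expect_equal(c(est$lower, est$median, est$upper), rep(0.4 * 350, 3))
  est <- mcInterval(c(100, 200), 0.1, 0.1, mode = "element")
  expect_equal(c(est$lower, est$median, est$upper), rep(30, 3))
  # empty area set: degenerate zero interval
  est <- mcInterval(numeric(0), 0, 1)
  expect_equal(c(est$lower, est$median, est$upper), c(0, 0, 0))
})

test_that("totals respect analytic bounds and verbose lengths", {
  set.seed(52)
  for (rep in 1:20) {
    n <- sample(1:8, 1)
    areas <- stats::runif(n, 10, 500)
    lo <- stats::runif(1, 0, 1); hi <- lo + stats::runif(1, 0, 2)
    for (mode in c("global", "element")) {
      tot <- mcInterval(areas, lo, hi, mode = mode, n_iter = 200,
                        verbose = TRUE)
      expect_length(tot, 200)
      expect_true(all(tot >= lo * sum(areas) - 1e-9))
      expect_true(all(tot <= hi * sum(areas) + 1e-9))
    }
  }
  expect_length(mcInterval(c(10), 0, 1, verbose = TRUE), 1000)
})

test_that("interval quantiles follow the definition and nest", {
  set.seed(53)
  tot <- mcInterval(100, 0, 1, n_iter = 1000, verbose = TRUE)
  set.seed(53)
  est <- mcInterval(100, 0, 1, n_iter = 1000, interval = 0.95)
  expect_equal(est$lower, unname(stats::quantile(tot, 0.025)))
  expect_equal(est$upper, unname(stats::quantile(tot, 0.975)))
  expect_equal(est$median, unname(stats::quantile(tot, 0.5)))
  # median of Uniform(0, 100) totals lands near 50
  expect_gt(est$median, 40); expect_lt(est$median, 60)
  set.seed(53)
  narrow <- mcInterval(100, 0, 1, n_iter = 1000, interval = 0.5)
  expect_gte(narrow$lower, est$lower)
  expect_lte(narrow$upper, est$upper)
})

test_that("doubling areas doubles interval endpoints", {
  areas <- c(120, 340, 90)
  set.seed(54); a <- mcInterval(areas, 0.1, 0.9)
  set.seed(54); b <- mcInterval(2 * areas, 0.1, 0.9)
  expect_equal(c(b$lower, b$median, b$upper),
               2 * c(a$lower, a$median, a$upper))
})

test_that("no2 sequestration follows the effective-area equation", {
  tab <- defaultAttributeTable()
  # 1000 m2 of trees: degenerate range 0.11 -> exactly 0.11
  trees <- rectCity(data.frame(
    x = 0, y = 0, w = 40, h = 25, land_use = "Trees",
    land_use_verbose = "Park", floors = 0, stringsAsFactors = FALSE))
  set.seed(55)
  expect_equal(no2Seq(trees, tab), 1000 * 0.11 / 1000)
  # all-zero green: 0
  zero <- tab; zero$pGreen <- 0
  set.seed(55)
  expect_equal(no2Seq(trees, zero), 0)
  # edible override: community garden counts edible_area, not pGreen
  cg <- rectCity(data.frame(
    x = 0, y = 0, w = 40, h = 25, land_use = "Community garden",
    land_use_verbose = "CG", floors = 0, edible_area = 200,
    stringsAsFactors = FALSE))
  degen <- tab; degen$no2_seq1 <- degen$no2_seq2
  set.seed(55)
  expect_equal(no2Seq(cg, degen), 200 * 0.09 / 1000)
  # analytic bounds on a mixed city over many seeds
  city <- mixedFixture()
  full <- fullTable()
  eff <- urbanECS:::.effectiveGreenArea(city, full)
  rows <- full[match(elements(city)$land_use, full$land_use), ]
  lo <- sum(eff * rows$no2_seq1) / 1000
  hi <- sum(eff * rows$no2_seq2) / 1000
  for (seed in 1:25) {
    set.seed(seed)
    v <- no2Seq(city, full)
    expect_gte(v, lo - 1e-12); expect_lte(v, hi + 1e-12)
  }
})

test_that("jobs count only commercial urban agriculture", {
  # no commercial gardens -> exactly 0 jobs
  base <- mixedFixture()
  set.seed(56)
  est <- edibleJobs(base)
  expect_equal(c(est$lower, est$median, est$upper), c(0, 0, 0))
  # one commercial garden of 1000 m2 growing area
  com <- rectCity(data.frame(
    x = 0, y = 0, w = 50, h = 40, land_use = "Commercial garden",
    land_use_verbose = "C", floors = 0, edible_area = 1000,
    stringsAsFactors = FALSE))
  set.seed(56)
  tot <- edibleJobs(com, verbose = TRUE)
  expect_length(tot, 1000)
  expect_true(all(tot >= 1000 * 0.000163 & tot <= 1000 * 0.022))
})

test_that("volunteers count community solutions, not private gardens", {
  # single 320 m2 community garden with default range
  cg <- rectCity(data.frame(
    x = 0, y = 0, w = 20, h = 16, land_use = "Community garden",
    land_use_verbose = "CG", floors = 0, edible_area = 320,
    stringsAsFactors = FALSE))
  set.seed(57)
  tot <- edibleVolunteers(cg, verbose = TRUE)
  expect_true(all(tot >= 320 * 0.00163 & tot <= 320 * 0.22))
  # degenerate range: 320 m2 at rate 0.1 -> exactly 32
  set.seed(57)
  est <- edibleVolunteers(cg, volunteers = c(0.1, 0.1))
  expect_equal(est$median, 32)
  # edible private gardens do not involve volunteers
  epg <- rectCity(data.frame(
    x = 0, y = 0, w = 20, h = 16, land_use = "Edible private garden",
    land_use_verbose = "G", floors = 0, edible_area = 200,
    stringsAsFactors = FALSE))
  set.seed(58)
  est <- edibleVolunteers(epg)
  expect_equal(est$upper, 0)
  set.seed(58)
  expect_equal(edibleJobs(epg)$upper, 0)
})

test_that("food production draws per-element yields within range", {
  tab <- defaultAttributeTable()
  # one hydroponic rooftop, 100 m2 growing area: totals in [900, 1900]
  hy <- rectCity(data.frame(
    x = 0, y = 0, w = 20, h = 10, land_use = "Hydroponic rooftop",
    land_use_verbose = "H", floors = 3, edible_area = 100,
    stringsAsFactors = FALSE))
  set.seed(59)
  tot <- foodProduction(hy, tab, verbose = TRUE)
  expect_length(tot, 1000)
  expect_true(all(tot >= 900 & tot <= 1900))
  # Monte-Carlo mean close to the analytic expectation 100 * 1.2
  cg <- rectCity(data.frame(
    x = 0, y = 0, w = 20, h = 10, land_use = "Community garden",
    land_use_verbose = "CG", floors = 0, edible_area = 100,
    stringsAsFactors = FALSE))
  set.seed(60)
  tot <- foodProduction(cg, tab, verbose = TRUE)
  expect_equal(mean(tot), 120, tolerance = 10 / 120)
  # degenerate ranges are exact; full area used when area_col is NULL
  degen <- tab; degen$food1 <- degen$food2
  set.seed(61)
  est <- foodProduction(cg, degen)
  expect_equal(c(est$lower, est$median, est$upper), rep(100 * 2.2, 3))
  set.seed(61)
  est <- foodProduction(cg, degen, area_col = NULL)
  expect_equal(est$median, 200 * 2.2)
  # user-supplied yield table
  set.seed(62)
  est <- foodProduction(cg, edible_df = data.frame(
    land_uses = "Community garden", food1 = 1, food2 = 1))
  expect_equal(est$median, 100)
  # no edible elements -> zero interval
  none <- rectCity(data.frame(
    x = 0, y = 0, w = 10, h = 10, land_use = "Grass",
    land_use_verbose = "P", floors = 0, stringsAsFactors = FALSE))
  set.seed(63)
  expect_equal(foodProduction(none, tab)$upper, 0)
})
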