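# Deterministic, seedable generator of fixture cities, neighbourhood
# layers and sky-view-factor rasters with known closed-form
# expectations, so every indicator and the scenario builder can be
# exercised without external data.

# Evaluate expr under a fixed seed without disturbing the caller's RNG
# stream.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic city
#'
#' A rectangular grid of square blocks separated by streets. Blocks are
#' assigned land uses by the configured fractions: buildings (land use
#' `"Rooftop"`, `land_use_verbose = "Residence"`, floors drawn from
#' `floors_range`, `flat_area = 0.8 * area`), `"Vacant"` plots,
#' `"Normal garden"`, parks (alternating `"Grass"` and `"Trees"`), and
#' `"Streets"` for the remainder plus the street strips between blocks.
#' When garden or vacant blocks exist, one of them becomes the city's
#' single pre-existing `"Community garden"` with
#' `edible_area = 0.5 * area`. Output is byte-identical for a given
#' config (including its `seed`) and leaves the caller's RNG stream
#' untouched.
#'
#' @param config a [SyntheticConfig-class].
#' @return A [CityModel-class]; all its land uses are covered by
#'   `defaultAttributeTable(impervious = TRUE)`.
#' @examples
#' city <- generateCity(syntheticConfig(blocks_x = 4, blocks_y = 4))
#' city
#' @export
generateCity <- function(config = syntheticConfig()) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  bx <- config@blocks_x; by <- config@blocks_y
  bs <- config@block_size; sw <- config@street_width
  pitch <- bs + sw
  nblocks <- bx * by
  counts <- c(building = .roundHalf(config@building_fraction * nblocks),
              vacant = .roundHalf(config@vacant_fraction * nblocks),
              garden = .roundHalf(config@garden_fraction * nblocks),
              park = .roundHalf(config@park_fraction * nblocks))
  while (sum(counts) > nblocks)          # rounding overshoot
    counts[which.max(counts)] <- max(counts) - 1
  uses <- rep(c("building", "vacant", "garden", "park", "street"),
              times = c(counts, nblocks - sum(counts)))

  .withSeed(config@seed, {
    uses <- uses[sample.int(nblocks)]
    floors_pool <- seq(config@floors_range[1], config@floors_range[2])
    blocks <- vector("list", nblocks)
    land_use <- character(nblocks); verbose <- character(nblocks)
    floors <- integer(nblocks)
    park_toggle <- TRUE
    for (k in seq_len(nblocks)) {
      i <- (k - 1) %/% bx; j <- (k - 1) %% bx
      x0 <- j * pitch; y0 <- i * pitch
      blocks[[k]] <- .rectRing(x0, y0, x0 + bs, y0 + bs)
      land_use[k] <- switch(uses[k],
        building = "Rooftop", vacant = "Vacant",
        garden = "Normal garden", street = "Streets",
        park = if (park_toggle) "Grass" else "Trees")
      if (uses[k] == "park") park_toggle <- !park_toggle
      verbose[k] <- switch(uses[k],
        building = "Residence", vacant = "Vacant", garden = "Garden",
        park = "Park", street = "Street")
      floors[k] <- if (uses[k] == "building")
        floors_pool[sample.int(length(floors_pool), 1)] else 0L
    }
    area <- rep(bs^2, nblocks)
    flat_area <- ifelse(uses == "building", 0.8 * area, area)
    edible_area <- rep(0, nblocks)
    # one pre-existing community garden, carved from a garden (or
    # vacant) block when available
    cg <- c(which(uses == "garden"), which(uses == "vacant"))[1]
    if (!is.na(cg)) {
      land_use[cg] <- "Community garden"
      verbose[cg] <- "Community garden"
      edible_area[cg] <- 0.5 * area[cg]
    }

    geoms <- blocks
    d <- data.frame(land_use = land_use, land_use_verbose = verbose,
                    floors = floors, area = area, flat_area = flat_area,
                    edible_area = edible_area, stringsAsFactors = FALSE)
    if (sw > 0) {
      W <- bx * pitch - sw; H <- by * pitch - sw
      sgeoms <- list(); k <- 0
      for (j in seq_len(bx - 1)) {      # full-height vertical strips
        k <- k + 1
        sgeoms[[k]] <- .rectRing(j * pitch - sw, 0, j * pitch, H)
      }
      for (i in seq_len(by - 1)) {      # horizontal segments per column
        for (j in seq_len(bx)) {
          k <- k + 1
          sgeoms[[k]] <- .rectRing((j - 1) * pitch, i * pitch - sw,
                                   (j - 1) * pitch + bs, i * pitch)
        }
      }
      sarea <- vapply(sgeoms, .geomArea, numeric(1))
      sd <- data.frame(land_use = "Streets", land_use_verbose = "Street",
                       floors = 0L, area = sarea, flat_area = sarea,
                       edible_area = 0, stringsAsFactors = FALSE)
      d <- rbind(d, sd)
      geoms <- c(geoms, sgeoms)
    }
    cityModel(d, geoms, crs = "EPSG:25831")
  })
}

#' Generate a neighbourhood layer partitioning a city
#'
#' `n` vertical slabs of equal width spanning the city extent, named
#' `"D1"` ... `"Dn"`, with the given populations.
#'
#' @param city a [CityModel-class].
#' @param n number of neighbourhoods.
#' @param inhabitants numeric vector of length `n`.
#' @return A [NeighbourhoodLayer-class].
#' @export
generateNeighbourhoods <- function(city, n = 2, inhabitants) {
  stopifnot(is(city, "CityModel"), n >= 1)
  if (length(inhabitants) != n)
    stop("inhabitants must have length n = ", n, call. = FALSE)
  bb <- apply(do.call(rbind, lapply(city@geometry, .geomBBox)), 2,
              range)
  xmin <- bb[1, "xmin"]; xmax <- bb[2, "xmax"]
  ymin <- bb[1, "ymin"]; ymax <- bb[2, "ymax"]
  brk <- seq(xmin, xmax, length.out = n + 1)
  geoms <- lapply(seq_len(n), function(k)
    .rectRing(brk[k], ymin, brk[k + 1], ymax))
  neighbourhoodLayer(paste0("D", seq_len(n)), inhabitants, geoms,
                     crs = city@crs)
}

#' Generate a synthetic sky-view-factor raster
#'
#' A plausible stand-in for a photometrically computed SVF: open ground
#' has SVF 1 and cells lose sky view with the floor-weighted density of
#' built volume within a kernel radius -- a monotone proxy, not a
#' hemispheric computation. Deterministic given the city.
#'
#' @param city a [CityModel-class].
#' @param cell_size cell edge, metres.
#' @param kernel_radius radius (m) within which buildings obstruct a
#'   cell's sky.
#' @param max_obstruction SVF value reached at the densest cell is
#'   `1 - max_obstruction`.
#' @return An [SvfGrid-class] aligned to the city bounding box.
#' @export
generateSvf <- function(city, cell_size = 20, kernel_radius = 60,
                        max_obstruction = 0.85) {
  stopifnot(is(city, "CityModel"), cell_size > 0)
  d <- city@data
  bb <- apply(do.call(rbind, lapply(city@geometry, .geomBBox)), 2,
              range)
  xmin <- bb[1, "xmin"]; xmax <- bb[2, "xmax"]
  ymin <- bb[1, "ymin"]; ymax <- bb[2, "ymax"]
  nc <- max(1L, ceiling((xmax - xmin) / cell_size))
  nr <- max(1L, ceiling((ymax - ymin) / cell_size))
  cx <- xmin + (seq_len(nc) - 0.5) * cell_size
  cy <- ymin + (nr - seq_len(nr) + 0.5) * cell_size
  built <- which(d$floors > 0)
  m <- matrix(1, nrow = nr, ncol = nc)
  if (length(built)) {
    cen <- t(vapply(city@geometry[built], .geomCentroid, numeric(2)))
    w <- d$floors[built] * d$area[built]
    px <- rep(cx, each = nr); py <- rep(cy, times = nc)
    dens <- numeric(length(px))
    for (b in seq_along(built)) {
      dist <- sqrt((px - cen[b, 1])^2 + (py - cen[b, 2])^2)
      near <- dist <= kernel_radius
      dens[near] <- dens[near] + w[b] / (1 + dist[near])
    }
    if (max(dens) > 0)
      m <- matrix(1 - max_obstruction * dens / max(dens),
                  nrow = nr, ncol = nc)
  }
  rasterGrid(m, xmin, ymin, cell_size, crs = city@crs, svf = TRUE)
}
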