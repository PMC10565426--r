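# Fixtures built in code: axis-aligned rectangle cities with hand-
# checkable geometry.

# Build a CityModel from a data.frame with x, y, w, h (rectangle origin
# and size) plus attribute columns.
rectCity <- function(df, crs = "EPSG:25831") {
  geoms <- lapply(seq_len(nrow(df)), function(i)
    urbanECS:::.rectRing(df$x[i], df$y[i],
                         df$x[i] + df$w[i], df$y[i] + df$h[i]))
  attrs <- df[, setdiff(names(df), c("x", "y", "w", "h")), drop = FALSE]
  cityModel(attrs, geoms, crs = crs)
}

# A 12-element mixed-use fixture: 4 residences, 2 parks, 3 vacant plots,
# 2 normal gardens, 1 community garden, on a simple grid.
mixedFixture <- function() {
  rectCity(data.frame(
    x = c(0, 120, 240, 360, 0, 120, 240, 360, 0, 120, 240, 360),
    y = rep(c(0, 110, 220), each = 4),
    w = 100, h = 100,
    land_use = c("Rooftop", "Rooftop", "Rooftop", "Rooftop",
                 "Grass", "Trees", "Vacant", "Vacant",
                 "Vacant", "Normal garden", "Normal garden",
                 "Community garden"),
    land_use_verbose = c(rep("Residence", 4), "Park", "Park",
                         rep("Vacant", 3), "Garden", "Garden",
                         "Community garden"),
    floors = c(3, 5, 2, 4, rep(0, 8)),
    edible_area = c(rep(0, 11), 320),
    stringsAsFactors = FALSE))
}

fullTable <- function() defaultAttributeTable(impervious = TRUE)
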