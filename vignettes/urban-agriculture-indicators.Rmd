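---
title: "Modelling urban agriculture scenarios and their ecosystem services"
author: "urbanECS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling urban agriculture scenarios and their ecosystem services}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbanECS)
```

`urbanECS` estimates what a city gains when parts of it grow food. This
vignette is the package's own account of the science: the data model,
each indicator's equations and assumptions, the stochastic treatment of
parameters, the synthetic fixture generator, and the numerical and
design choices made where more than one reading was defensible.

## The urban representation

Every computation consumes a `CityModel`: polygons in a projected CRS
(metres — the package refuses geographic coordinates outright, since
every formula uses metric areas and distances) with six attributes:

* `land_use` — the category driving all parameter lookups;
* `land_use_verbose` — a free category, used e.g. to mark residences;
* `floors` — building height in storeys (0 for unbuilt land);
* `area` — m²; `flat_area` — the m² with slope below 5°, which is what
  a rooftop or plot can realistically offer to planters;
* `edible_area` — the m² actually growing edible plants (0 outside
  urban agriculture).

A companion attribute table (`defaultAttributeTable()`) carries, per
land use, the green fraction `pGreen`, ranges for NO₂ sequestration
capacity (µg s⁻¹ m⁻²), yield (kg m⁻² yr⁻¹) and SCS curve number, and
four logical flags. Ranges encode parameter uncertainty: every draw is
uniform within its range, so all values in a range are considered
equally plausible — an intentionally weak assumption suited to the
literature-derived bounds the defaults come from.

Two choices deserve comment:

* **Flag membership.** The published attribute sets behind the flags
  are not fully documented anywhere; we fixed them from the purpose of
  each land use: the five urban-agriculture types are `edible` (and
  thus rainwater `harvest`ers, together with raised beds);
  community gardens, arable land, permanent crops, grass and trees are
  `public` green; edible private gardens and normal gardens are
  `private`. Users can override any flag by editing the table.
* **Impervious rows.** The reference table covers the fourteen green
  typologies only. Real and synthetic cities also contain rooftops and
  streets; rather than silently skipping them (which hides data
  errors — unknown land uses are a hard error by design),
  `defaultAttributeTable(impervious = TRUE)` appends zero-green,
  curve-number-98 rows for `Rooftop`, `Streets` and `Building`.

## Scenario generation

`setScenario()` converts private gardens, vacant ground plots and
rooftops into edible private gardens, community/commercial gardens, and
rooftop/hydroponic gardens respectively. For each class:

1. the *assumed* conversion count is `round(p × #candidates)`
   (half-away-from-zero), counted over **all** candidates of the source
   land uses — this matches the user-facing message, which compares
   what was assumed with what was possible;
2. only candidates whose `area_field` (default `flat_area`) reaches the
   class minimum (10 m² gardens, 100 m² plots and rooftops) are
   eligible; a shortfall converts everything eligible and reports
   `"Only k … out of n assumed satisfy the 'min_area_…'"`;
3. commercial conversions (`round(pCommercial × converted)`) take the
   *largest* eligible elements — commercial initiatives can acquire the
   best spots — and the community remainder is drawn uniformly from the
   rest. The commercial rule covers ground plots and rooftops alike
   (hydroponic rooftops are the commercial rooftop technology); private
   gardens are personal and never commercial;
4. each converted element receives
   `edible_area = U(lo, hi) × area_field`; geometry, ids, `floors` and
   all other attributes are untouched, so element count and total area
   are conserved exactly.

Uniform selection is implemented as "take the first *n* of one random
permutation of the eligible pool", which makes conversion sets nested
in `p` under a common seed — convenient for scenario ladders.

## The indicators

### Urban heat island

Per raster cell `i`,

$$UHI_i = (2 - SVF_i - Fveg_i)\,
  \left(\frac{Q_{ql}\,\Delta T^3}{C_{air} P_{air} U}\right)^{1/4}$$

where `SVF` is the sky view factor (supplied as a raster, typically
computed by a GIS toolchain), `Fveg` the vegetation fraction, and the
meteorological defaults (`Qql = 6.11` W/m²/h, `Cair = 1007`,
`Pair = 1.14` kg/m³, `Tmax = 30.8` °C, `Tmin = 20` °C, `U = 2.77` m/s)
describe a Mediterranean summer day. The printed rendering of this
diagnostic equation is typographically ambiguous about what sits under
the fourth root; we implement the reading consistent with the
diagnostic-equation literature it descends from (the whole
meteorological quotient), and expose the cell formula separately
(`uhiCellValues()`) so it can be audited in isolation. The
meteorological units are dimensionally loose in the source; the
defaults are used as plain numbers, as the reference implementation
does.

`Fveg` is rasterized from the city by *cell-centre sampling*: each cell
takes the `pGreen` of the polygon containing its centre, overridden by
`edible_area/area` for urban-agriculture elements, 0 over no polygon.
Centre sampling (rather than area-weighted coverage) keeps the
operation deterministic and matches common vector→raster defaults.
Nodata SVF cells are excluded from every statistic; cells where
`2 − SVF − Fveg` would be negative (impossible for in-range inputs,
possible as numerical noise) are floored at 0.

### Runoff prevention

The SCS curve-number method for a 24-h design storm (default
`rain = 85` mm): `S = 25400/CN − 254` (metric form; the CN is drawn
uniformly within the land use's range per element) and
`Q = (P − I_a)²/((P − I_a) + S)` for `P > I_a`, else 0. The classical
`I_a = 0.2 S` is augmented with harvested rainwater:

$$I_a = 0.2\,S + \min\{R_h, W_s\}/area$$

`R_h` (litres) is the rain fallen on *catchment* surfaces: elements
within `harvest_dist` (10 m) of the harvester's boundary, with strictly
more floors, whose land use is not edible. `W_s` (litres) is the tank
capacity, `U(0, 45)` L per m² of harvester surface — the tank-size
units follow the descriptive text (L/m², proportional to surface), not
the terser annotation elsewhere. Three further choices:

* the harvested term is litres while `I_a` is mm, so it is divided by
  the element's area (1 L/m² = 1 mm) — the only dimensionally
  consistent bridge;
* every catchment element credits **only its nearest harvester**, so
  the same rain is never stored twice (mass conservation); a
  double-counting variant would inflate `rainharvest`;
* the city-scale figure is the **area-weighted** mean of per-element
  `Q` — a plain element mean would let tiny polygons dominate a
  physically areal quantity.

Reported alongside: `rainfall = P × Σarea/1000` (m³; identical across
scenarios of one footprint, a useful conservation check) and
`rainharvest = Σ min(Rh, Ws)/1000` (m³).

### Green accessibility and green per capita

`greenDistance()` measures straight-line boundary-to-boundary distances
from each residence footprint to the closest `public` green element of
at least `min_area` (5000 m² and 300 m defaults, after the WHO
recommendation). Euclidean rather than network distance is a deliberate
simplification — the geometric stack has no street graph — and
footprints rather than centroids make "overlapping the park" exactly
zero. Green elements are tested individually against `min_area`;
adjacent green polygons are not dissolved first, so a park split into
several cadastral pieces may be excluded — a documented parity caveat.

`greenCapita()` counts full polygon areas (not `pGreen`-weighted — the
notion is "green areas", not canopy). In neighbourhood mode, elements
straddling boundaries are apportioned by intersection area
(Sutherland–Hodgman clipping, exact for convex neighbourhood polygons;
concave districts would need decomposition first). The equity figure is
the max/min of neighbourhood m²/person after dropping districts below
`min_inh` inhabitants (unpopulated industrial districts otherwise
dominate the ratio).

### NO₂, jobs, volunteers, food

All four are linear in area with stochastic rates:

* `no2Seq()` returns `Σ a_i · cap_i / 1000` with `cap_i` drawn per
  element and `a_i` the *effective* green area (`area × pGreen`,
  overridden by `edible_area` for edible land uses). One draw per call,
  one figure per scenario. The /1000 scaling and the g/s label are
  reproduced exactly as the method prints them, without re-deriving the
  unit chain, which is internally inconsistent in the source material.
* `edibleJobs()` / `edibleVolunteers()` run 1,000 Monte-Carlo
  iterations of `Σ a_i · k` over the commercial
  (`Commercial garden`, `Hydroponic rooftop`) and community
  (`Community garden`, `Rooftop garden`) growing areas respectively,
  with **one `k` per iteration** (`k ∈ U(0.000163, 0.022)` jobs/m²,
  `U(0.00163, 0.22)` volunteers/m²): the rate, not the element mix, is
  the uncertain quantity. Edible private gardens are personal and count
  for neither.
* `foodProduction()` draws the yield **per element** each iteration
  from its category's `[food1, food2]` and totals `Σ y_i a_i` (kg/yr),
  over `edible_area` (or full `area` when `area_col = NULL`).

Quantiles everywhere — six-number summaries, Monte-Carlo intervals —
use linear interpolation between order statistics (the type-7
convention), so `interval = 0.95` returns the empirical 2.5% / 50% /
97.5% points; the tail quantiles are always derived from `interval`
rather than fixed.

## The synthetic fixture generator

`generateCity()` emulates the structure of a real urban layer on a
block grid: square blocks (default 12 × 12 of 80 m with 8 m streets,
≈ 290 elements) assigned by configurable fractions to residential
buildings (1–6 floors), vacant plots, normal gardens and parks, with
street strips tiling the remaining extent exactly and one pre-existing
community garden (on a garden or vacant block, when one exists — a
purely-park configuration stays purely park so that areas close in
closed form). Defaults were chosen once to resemble a dense European
residential neighbourhood at a size where the full indicator suite
runs in seconds: half the blocks built, the rest split between vacant
land, gardens and parks, 40 inhabitants per residential block.

`generateSvf()` is a monotone proxy, not a hemispheric computation:
SVF is 1 on open ground and decreases with the floor-weighted built
volume within a 60 m kernel, scaled so the densest cell reaches 0.15.
It has the right range, alignment and qualitative structure for
testing; it is **not** photometrically accurate, so tests passing on it
say nothing about absolute UHI levels in a real city — only about the
equation, its monotonicity and its scaling. Likewise the generator's
rectangular geometry never exercises concave or holed polygons at the
indicator level (the geometry layer is tested on those separately), and
its uniform block sizes make eligibility thresholds sharper than in
real cadastres.

`generateNeighbourhoods()` partitions the extent into vertical slabs
with given populations — enough to exercise apportionment and the
equity ratio with hand-computable expectations.

## Numerical choices and degenerate inputs

* Geometry is planar and exact: shoelace areas (even-odd rule for holes
  and multipolygons), segment-wise boundary distances with bounding-box
  pruning, convex clipping for intersections. Point-in-polygon is
  cross-checked against an independent implementation (`mgcv::in.out`)
  in the tests.
* An `area` attribute disagreeing with the recomputed polygon area by
  more than 5% warns (and keeps the attribute); beyond-range
  `edible_area`/`flat_area` are hard errors.
* Empty cities, empty Monte-Carlo inputs and zero-rain storms all have
  defined results (zero intervals, zero triplets); an all-nodata SVF,
  an empty summary vector, zero qualifying green areas and an
  all-excluded neighbourhood set are errors, because their statistics
  are undefined rather than zero.
* Degenerate ranges (`lo = hi`) short-circuit nothing: they flow
  through the same code paths and reproduce closed forms exactly,
  which the test suite exploits throughout.
* Reproducibility: generators take explicit seeds and restore the
  caller's RNG state; indicators use R's global stream (`set.seed()`
  before each call); `runReport()` splits one master seed into named
  substreams per scenario × indicator, so adding an indicator never
  perturbs another's draws and a report is byte-identical under one
  seed.

## Problem sizes

The shipped tests and the acceptance script run on the default
≈ 290-element city with a 20 m SVF grid (≈ 2,800 cells), 1,000
Monte-Carlo iterations per stochastic indicator, and scenario ladders
of three scenarios; the full suite completes in well under a minute on
one core. These sizes were chosen as the smallest at which every
eligibility message, harvesting interaction and equity contrast in the
test suite actually occurs.

## Limitations

The model is 2.5-D (floors, but no vertical farming or facade
greening); indicators measure benefits only (no heavy-metal uptake,
nutrient runoff or gentrification effects); accessibility is Euclidean;
the harvesting catchment model is nearest-assignment rather than a
hydraulic network; and the synthetic fixtures, while structurally
faithful, are not a substitute for a surveyed urban layer — parity
against a real city requires supplying its own GeoJSON/ASCII-grid
inputs.
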