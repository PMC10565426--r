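Package: urbanECS
Title: Scenario Modelling and Ecosystem-Service Indicators for Urban
    Agriculture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models edible-city solutions (urban agriculture) on a polygon
    representation of a city and estimates eight ecosystem-service
    indicators with Monte-Carlo uncertainty: urban heat island from a
    sky-view-factor raster, SCS curve-number runoff with rainwater
    harvesting, accessibility of public green areas, nitrogen dioxide
    sequestration, jobs created, volunteers involved, green area per
    capita, and food production. Includes a scenario generator that
    converts private gardens, vacant plots and rooftops into five types
    of urban-agriculture solution, a deterministic synthetic-city
    generator for testing, and plain-text GIS readers and writers
    (GeoJSON vectors, ESRI ASCII grid rasters).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), mgcv, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'geometry.R'
    'AllClasses.R'
    'AllGenerics.R'
    'attribute-table.R'
    'summary-stats.R'
    'io.R'
    'scenario.R'
    'uhi.R'
    'runoff.R'
    'green.R'
    'stochastic.R'
    'synthetic.R'
    'report.R'
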