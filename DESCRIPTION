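Package: siclimate
Title: Coupled Global Carbon-Silica Cycle Modelling of Marine Reverse Weathering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-box ocean plus atmosphere biogeochemical model of the coupled
    global carbon and silica cycles, built to explore how the collapse of the
    marine biological silica factory can reroute dissolved silica into authigenic
    clay formation (reverse weathering) and thereby recycle CO2 within the
    ocean-atmosphere system. Includes seawater carbonate chemistry, delta-13C
    bookkeeping, Michaelis-Menten biogenic silica production, saturation-state
    clay and inorganic silica precipitation laws, a three-phase mass-extinction
    scenario driver, Monte Carlo parameter ensembles filtered against
    sea-surface-temperature target curves, an end-member detrital-authigenic
    sediment mixing model, mineral-abundance and chert-occurrence analyses, and
    synthetic-data generators for all tabular inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
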