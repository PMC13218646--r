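Package: dlumr
Title: Destination and Land-Use Mix Indicators for Walkability Research
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the twelve destination and land-use mix (DLUM) spatial
    indicators of neighbourhood destination accessibility used in built
    environment and physical activity research, within 1-km street-network
    sausage buffers around home locations. Provides a planar street-network
    model (snapping, network-distance reachability, intersection counting),
    sausage-buffer polygon construction, parcel aggregation into per-buffer
    land-use summaries, the two land-use-mix entropy indices and their hybrid
    intensity-by-heterogeneity combinations, cross-site ranking and rank
    correlation machinery, a construct-validity association harness with
    permutation tests, and a seeded synthetic-city generator (grid street
    fabric, single-use parcels, dwelling counts, participants, perceived
    proximity responses, and physical activity outcomes) so the whole pipeline
    is testable without confidential geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    polyclip,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
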