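Package: fptseg
Title: First-Passage-Time Segmentation of Central-Place Forager GPS Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to segment nightly GPS tracks of central-place foragers
    (developed for nectar-feeding bats commuting between a maternity roost and
    distant flower patches) into commuting and foraging flight using First
    Passage Time (FPT): per-relocation passage times at a circle of radius r,
    the variance-of-log-FPT scale-selection profile S(r), and threshold
    classification of log-FPT at the population-mean optimal radius.  Nights
    are further decomposed into roost-to-roost trips, and foraging areas are
    delineated, sized from the S(r) peak radius, and characterized by distance
    from the roost, search-time effort and majority land-cover habitat.  A
    seeded two-mode correlated-random-walk simulator with a GPS duty-cycle,
    error and dropout model provides ground-truthed tracks plus matching
    land-cover and elevation rasters, so the whole chain is testable without
    field data.  Includes Movebank-style CSV input/output, an in-package UTM
    projection, ESRI ASCII grid rasters, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
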