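Package: betadrivers
Title: Partitioning the Drivers of Arthropod Community Composition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Attributes between-site variation in arthropod assemblage
    composition to plant species composition, land cover, climate, space,
    plant-derived Ellenberg indicator profiles, and monophage host-plant
    links. Implements presence-absence community assembly, Sorensen and
    Euclidean dissimilarities, distance-based redundancy analysis with
    adjusted R-squared, 2- to 4-set variation partitioning, Mantel
    permutation tests, indicator-class frequency profiles, and a
    randomization null comparing host-plant subsets against random plant
    subsets of equal size. Includes a niche-based synthetic community
    generator with configurable driver mixtures so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
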