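Package: bioturbr
Title: Bioturbation Analysis of Fluorescent Sediment Profile Images from
    Clam Microcosm Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify bioturbation by burrowing bivalves from
    fluorescent sediment profile images (f-SPI) and to analyse the
    accompanying water-nutrient chemistry of replicated microcosm
    experiments. Segments pink luminophore tracer particles from RGB
    profile photographs, detects the sediment-water (or, for undisturbed
    controls, sediment-luminophore) interface, flattens it, and computes
    the maximum, median and mean mixed depth of particle redistribution
    plus surface boundary roughness. Implements one-way PERMANOVA
    (pseudo-F with Monte-Carlo or exhaustive permutation p-values),
    pairwise permutation t contrasts and principal component ordination
    for the experimental design, and ships a calibrated synthetic
    microcosm generator (profile images with known particle-depth ground
    truth, nutrient time series) so the full pipeline is testable
    end-to-end without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
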