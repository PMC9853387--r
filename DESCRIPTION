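Package: cytocruise
Title: Underway Automated Flow Cytometry of Marine Prokaryote Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Analysis pipeline for underway (ship-based) automated flow
    cytometry of SYBR-Green-stained marine prokaryotes. Reads and writes FCS
    3.x cytograms, collates time-stamped run folders into a cruise sample set,
    and carries each cytogram through acquisition thresholding, asinh
    transformation, polygon gating, global fluorescence normalization and
    seeded subsampling. From the processed events it estimates cell
    concentrations (with diel day/night contrasts and exponential net growth
    rates), bead-calibrated cell size and carbon biomass, binned cytometric
    fingerprints with Hill-number phenotypic diversity and Bray-Curtis beta
    diversity, and self-organizing-map population structure (HNA/LNA
    prokaryotes and photosynthetic cells) with the HNA/LNA activity ratio.
    A synthetic-campaign generator emulates the multi-population event clouds,
    Poisson event counts, diel cycles, station structure and
    environment-abundance coupling of a real cruise, so the whole pipeline is
    testable against known ground truth.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    mgcv,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
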