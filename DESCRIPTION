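Package: bathyrich
Title: Bathymetric Species Richness Surfaces from Occurrence Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds global latitude-by-depth species richness surfaces for
    benthic faunas from georeferenced occurrence records. Occurrences are
    cleaned against a catalogue of described depth and latitudinal limits,
    missing depths are imputed from bathymetry, and species ranges are filled
    by informed interpolation: latitudinal gaps between records are bridged
    only where the sea-floor depth envelope overlaps a species' catalogued
    bathymetric limits and no known range disjunction intervenes. Downstream
    stages compute richness and sampling-effort grids across shallow, bathyal
    and abyssal strata, interpolation-uncertainty maps, Sorenson beta
    diversity with UPGMA clustering of faunal provinces, sea-floor
    environmental cell tables with Martin-curve particulate organic carbon
    export, and driver inference via all-subsets Poisson regression with a
    sampling-effort offset, random-forest permutation importance, partial
    dependence, and piecewise-linear thermal-threshold detection. A synthetic
    world generator with exported ground truth makes the whole pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
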