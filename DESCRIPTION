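Package: specdiv
Title: Spectral Functional Diversity and Forest Drought Response Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps trait-based functional richness and evenness of forest
    canopies from multi-band surface-reflectance rasters and relates them to
    drought resistance, recovery and resilience derived from multi-year
    changes in the normalized difference water index (NDWI). Provides the
    red-edge chlorophyll index (CIre), carotenoid/chlorophyll index (CCI)
    and normalized difference infrared index (NDII) as trait proxies, a
    circular moving-window engine computing alpha-shape hull volumes
    (functional richness) and minimum-spanning-tree regularity (functional
    evenness) in three-dimensional trait space, cloud/shadow/forest masking
    with robust median-outlier thresholds, equal-range binning with weighted
    univariate model selection, and sequential sum-of-squares variance
    partitioning across diversity bins and geographic subregions. A
    synthetic-landscape generator with known ground truth makes every stage
    of the pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
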