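Package: edreconstruct
Title: Reconstruct 1940 Census Enumeration Districts from Geocoded Address Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds "virtual" 1940 census enumeration-district polygons from
    clusters of geocoded street addresses and assigns historical HOLC
    ("redlining") neighborhood grades by areal predominance. Provides readers
    for Geographic Reference File style address tables, a pluggable geocoder
    interface with confidence-radius, result-type and county-bounds exclusion
    rules, 10-nearest-neighbour exponential-decay cluster weighting, weighted
    centroids with interquartile-range and absolute-radius outlier trimming,
    convex/alpha hull polygon construction in Web Mercator, centroid-based
    pairing against reference district polygons, grade concordance
    cross-tabulation, and a synthetic-city simulator so the full pipeline is
    testable without external data services.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    polyclip,
    deldir,
    sp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
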