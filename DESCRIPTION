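Package: ddparcel
Title: Spatially Contiguous Parcellation of Connectivity Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Divides the elements of a spatial map into contiguous
    parcels with homogeneous connectivity.  A distance-dependent Chinese
    restaurant process prior over neighbour links confines the search to
    spatially connected partitions, a conjugate Normal-Inverse-chi-squared
    block likelihood scores the between-parcel connectivity, and collapsed
    Gibbs sampling returns the maximum a posteriori parcellation together
    with the number of parcels.  Includes spatially constrained baseline
    methods (edge thresholding, normalized cut, region growing, Ward
    linkage, random merging), synthetic grid and spiral generators,
    normalized mutual information and variance-explained scoring, and
    preprocessing for origin-destination flow tables (small-unit merging
    and chance normalization).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
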