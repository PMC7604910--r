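Package: xtalclust
Title: Pre-Clustering of Crystallographic Multi-Data Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions large collections of related crystallographic data sets
    (fragment- and drug-screening "multi-data sets") into homogeneous clusters
    before downstream per-voxel statistical analysis. Builds average reflection
    and C-alpha coordinate sets, scales each data set in equal-volume resolution
    shells to remove global isotropic B-factor effects, correlates per-pair
    difference series with a bounded Pearson coefficient, embeds the resulting
    correlation matrix by singular value decomposition, and assigns recursive
    subclusters. Also resolves indexing ambiguities, removes outlier models, and
    collapses symmetry-related coordinate frames. Ships a synthetic multi-data-set
    generator with planted cluster structure for end-to-end testing, and a
    command-line entry point.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
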