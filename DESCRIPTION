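Package: braincensus
Title: Stereoscopic Neuron Census for Whole-Brain Microscopy Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects, localizes and counts fluorescently labeled neuronal
    somas in large anisotropic 3D light-microscopy volumes using guard-zone
    block processing with exactly-once merging, assigns detections to
    anatomical regions from a co-registered label volume, and computes
    regional distribution statistics (counts, volumes, densities,
    nearest-neighbor nuclei distances, cortical layer profiles), detection
    accuracy metrics (recall and precision against ground truth with optimal
    point matching), and a soma-morphometry similarity analysis (six shape
    features, PCA, concentration filtering, intra-region dispersion and
    pairwise significance tests). Ships a synthetic labeled-brain generator
    that emulates the statistical structure of such imaging data, so the
    whole pipeline is testable without any raw dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tiff,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
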