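Package: demixscale
Title: Multi-Scale Constrained NMF Demixing of Calcium Imaging Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Source extraction for calcium imaging movies by constrained
    non-negative matrix factorization (CNMF) with spatial locality patches,
    accelerated by temporal and spatial decimation of the video.  Includes
    fast HALS block-coordinate updates, noise-constrained sparse non-negative
    spike deconvolution under AR(2) calcium dynamics, a two-phase imaging
    protocol in which neuron shapes learned at full resolution demix heavily
    spatially decimated (and interleaved dual-grid) video, truncated-SVD and
    randomized sketch compression for comparison, and a ground-truth
    synthetic fluorescence scene generator used for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    tiff,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
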