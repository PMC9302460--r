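Package: megmvpa
Title: Spatiotemporal Searchlight Decoding of Sensor-Level MEG Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for time-resolved multivariate pattern analysis of
    epoched magnetoencephalography (MEG) sensor data. Implements the
    synthetic planar gradient transform for axial gradiometer arrays,
    spatiotemporal searchlight feature extraction over a sensor neighbor
    graph, Gaussian naive Bayes decoding with repeated stratified
    cross-validation and random undersampling, stratified (constrained)
    permutation nulls with Z-standardization of decoding accuracy, and
    group-level cluster-based permutation inference over channels and
    time. A simulation module generates sensor layouts, psycholinguistic
    stimulus tables with controlled covariate correlations, and epoched
    MEG-like data with injected class effects, so that effect latency and
    topography recovery can be verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
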