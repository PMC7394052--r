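Package: gaitmuscnet
Title: Muscle Synergies and Multiplex Coherence Networks During Walking
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline from multichannel gait surface EMG and
    kinematics to arm-leg coordination modes, muscle synergies extracted by
    non-negative matrix factorization with rank selection, bias-corrected
    intermuscular coherence decomposed into frequency components, and
    multiplex muscle networks with community structure and graph metrics.
    Includes a synthetic-data generator with planted ground truth (synergies,
    band-limited common inputs, 2:1/transition/1:1 arm-leg frequency locking,
    heel-strike events) so every stage is testable without recorded data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
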