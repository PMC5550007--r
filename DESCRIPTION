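Package: neurofb
Title: Simulated fMRI Neurofeedback Environment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A simulation testbed for closed-loop fMRI neurofeedback. Provides
    an orientation-tuned voxel model of early visual cortex measured through
    hemodynamic-style causal temporal filters (impulse, canonical HRF, pure
    delay, moving-average blur), sparse multinomial pattern decoders that turn
    voxel patterns into feedback scores, cognitive target-search protocols with
    continuous or intermittent feedback and pluggable agents, and a
    reinforcement-learning model of automatic conditioning of spontaneous
    activity with explicit internal temporal models. Includes Monte-Carlo
    experiment drivers, learning-curve aggregation and categorization, and
    correlation analysis of conditioned activity patterns against true
    stimulus patterns and classifier weight maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
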