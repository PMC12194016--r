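Package: lftimes
Title: Log-File Time Decomposition for Construction-Based Matrix Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing click-stream event logs from computer-based,
    construction-based figural matrix tests. Decomposes time on task into
    onset, interrule and intrarule components, derives structuredness scores
    (rule jumps), practice-related acceleration, and motivation indicators
    (response to difficulty, incomplete attempt propensity), and provides the
    accompanying statistical stage: quadratic time-on-task regression,
    hierarchical agglomerative clustering of processing strategies with
    silhouette-based model selection and bootstrap stability, a parallel
    mediation path model with bootstrap confidence intervals and maximum
    likelihood fit indices, hierarchical regression with incremental variance
    decomposition, and crossed random-intercept mixed models. A synthetic
    cohort generator with full ground truth supports validation of the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    car,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
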