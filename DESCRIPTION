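Package: capdyn
Title: Co-Activation Pattern Dynamics of Parcellated BOLD Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: State-trait analysis of resting-state brain dynamics via
    co-activation patterns (CAPs). Implements split-half permutation CAP
    discovery with k-means++ / Lloyd clustering and silhouette-elbow model
    selection, basis-CAP aggregation and one-to-one matching, per-subject
    temporal metrics (fractional occupancy, dwell time) under motion
    scrubbing, ICC(2,1) test-retest reliability and state-trait variance
    decomposition, neural and behavioral dimension reduction with
    permutation significance, and a cross-validated neuro-behavioral
    association model. Ships a Markov-switching synthetic cohort generator
    with full ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
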