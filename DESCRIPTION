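Package: longdasim
Title: Simulation of Longitudinal Differential Abundance for Microbiome
    Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates longitudinal microbiome feature trajectories for
    control and treatment groups from a multivariate (optionally
    zero-truncated) normal model with user-specified mean-trend families
    (polynomial, oscillating, hockey-stick), within-subject correlation
    structures (AR(1), compound symmetry, independent), missing-data
    induction, and equidistant or asynchronous sampling schedules.
    Includes trend-recovery performance metrics (cosine similarity,
    Euclidean and normalized Euclidean distance, sensitivity and
    specificity over repetitions) and a factorial parameter-sweep harness
    with a pluggable detector interface for benchmarking longitudinal
    differential-abundance estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    biomformat,
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
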