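Package: flmm
Title: Functional Linear Mixed Models for Trial-Level Photometry Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits functional linear mixed models to trial-structured
    signals sampled on a common time grid, such as event-aligned fiber
    photometry traces. A Gaussian linear mixed model is fit at every trial
    time-point, the raw coefficient functions are smoothed with penalized
    B-splines, and pointwise as well as simultaneous (joint) 95% confidence
    bands are constructed from a method-of-moments estimate of the
    cross-time-point covariance of the estimators, supporting nested
    random effects. Includes a synthetic-data generator for nested
    longitudinal functional designs, windowed summary-measure baselines
    (AUC, paired t-test, scalar mixed models), and seeded coverage and
    power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    methods,
    splines,
    stats,
    utils,
    jsonlite,
    ggplot2,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
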