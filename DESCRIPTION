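Package: practiceAdjust
Title: Dissociating Practice Effects from Development in Accelerated
    Longitudinal Cognitive and Motor Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and removing practice (retest learning)
    effects from accelerated-longitudinal (cohort-sequential) studies of
    cognitive and motor performance. Provides composite Z-score construction
    from baseline-standardized test measures, penalized-spline ("smoothed
    age") and linear age trajectory fits with likelihood-ratio model
    comparison, per visit-pair learning estimation (delta R-squared index,
    age-by-visit and sex-by-visit interactions), a cumulative extension of
    the twice-minus-once-tested adjustment that subtracts age-dependent
    learning estimated from per-visit cross-sectional fits, developmental
    trajectory re-estimation on adjusted data with linear-versus-smooth
    shape tests and slope comparisons, a synthetic cohort generator with
    known ground truth, and a configuration-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    nlme,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
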