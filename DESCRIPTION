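Package: stochtrans
Title: Partitioning Stochastic Population Dynamics into Asymptotic and
    Transient Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for decomposing the dynamics of stage-structured
    populations in variable environments into asymptotic growth (the
    dominant eigenvalue of the annual projection matrix) and transient
    amplification or attenuation (reactivity, driven by deviation of the
    current stage structure from the stable stage structure).  Provides
    eigen-analysis and ergodicity diagnostics for projection matrices,
    stochastic simulation under i.i.d. environmental draws with burn-in,
    per-population variance partitioning of simulated growth, a generator
    of synthetic plant-demography databases with controlled statistical
    structure, and hierarchical mixed-model comparisons of transient
    contributions across growth forms and matrix dimensions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
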