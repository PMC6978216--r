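Package: svdnet
Title: Structural Brain Network Decline and Cognition in Cerebral Small
    Vessel Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how cerebral small vessel disease disrupts
    structural brain networks and cognition over time. Builds weighted
    structural connectomes from streamline records (sum of inverse
    streamline lengths with a seed-density scale factor, thresholded to
    suppress spurious edges), computes global graph measures and the
    rich-club / feeder / peripheral connection-class decomposition,
    constructs composite cognition scores (z-anchored to the baseline
    population, with speed-accuracy trade-off scores and Stroop
    interference), and fits the longitudinal statistics linking white
    matter hyperintensity burden to network decline, cognitive decline and
    dementia: repeated-measures change tests, covariate-adjusted group
    differences, standardized-beta regressions, and single-mediator path
    models with bootstrap inference. A calibrated synthetic two-wave
    cohort generator with known injected effects provides a ground-truth
    test bed for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
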