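Package: oculonet
Title: Correlation Networks Linking Oculomotor Performance and Cognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building two-domain correlation networks from
    antisaccade and Go/NoGo eye-movement recordings and neurocognitive test
    batteries. Provides a composite velocity/dispersion event detector for
    250 Hz gaze streams, trial scoring with a saccade-latency filter,
    per-subject summary measures, the classical statistical layer (Student's
    t, variance F-test, Kruskal-Wallis, Pearson correlation, regression
    influence diagnostics for subject exclusion), and construction of full
    (significance-gated) and thresholded (|r| > 0.4) networks with degree
    centrality. A synthetic-cohort generator with calibrated latency,
    accuracy and cognitive-score distributions stands in for raw clinical
    recordings, and the published correlation tables ship as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
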