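Package: gtrel
Title: Generalizability-Theory Reliability for Trial-Level Psychophysiological Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generalizability (G) and decision (D) study analysis for
    trial-level psychophysiological scores such as single-trial ERP
    amplitudes, per-split heart-rate-variability indices, or rectified EMG
    magnitudes. Estimates variance components by expected mean squares in
    balanced designs and by Bayesian multilevel models (including
    location-scale heteroscedastic residuals and non-Gaussian score
    families) in unbalanced designs, then computes generalizability and
    dependability coefficients, intraclass correlations, coefficients of
    equivalence and stability, cut-score dependability, split designs,
    difference-score reliability with concurrent error covariances, and
    sample-size projections with posterior uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    coda,
    rjags
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
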