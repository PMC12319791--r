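Package: emokinetics
Title: Encoding and Decoding Dynamic Emotions from Naturalistic fMRI ROI Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how dynamically rated perceived and
    felt emotions are represented in regional brain activity during naturalistic
    movie viewing. Converts sparse continuous emotion ratings into
    hemodynamic-response-convolved design matrices, screens emotions with a
    combined intersubject-reliability statistic and its permutation threshold,
    conditions region-of-interest BOLD time series (percent signal change,
    nuisance regression, equiripple FIR bandpass), fits cross-validated linear
    encoding and decoding models with max-statistic permutation control of the
    family-wise error rate, maps single-emotion responses with circular-shift
    surrogate nulls, and clusters emotions by the cross-run spatial similarity
    of their response patterns. Includes a synthetic-data generator with known
    ground truth so every stage is testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    ape,
    optparse
Config/testthat/edition: 3
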