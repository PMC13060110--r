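Package: capconn
Title: Time-Resolved Directed Connectivity via Water-Filling Channel Capacity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates directed effective connectivity between regional neural
    time series by modelling each ordered region pair as a finite-impulse-response
    Gaussian channel. Channel coefficients are fitted per sliding window by
    nonnegative least squares with information-criterion order selection, and the
    channel capacity is computed by discretized water-filling over the
    equivalent-input-noise spectrum. Includes sliding-window correlation and
    prediction-correlation measures, statistical validation procedures
    (task-sensitivity testing with FDR control, directional-asymmetry specificity
    testing, bootstrap cross-modal correspondence), k-means brain-state clustering
    with elbow selection and centroid alignment, and synthetic-data generators for
    all of the above.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
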