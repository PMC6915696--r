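Package: polyQavg
Title: Average PolyQ Length and CAG Repeat Instability from Immunoassay and
    Fragment-Analysis Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the average polyglutamine (polyQ) tract length in a
    mixed population of huntingtin proteins from the ratio of polyQ-antibody
    to total-antibody sandwich-immunoassay signals. Fits four-parameter
    logistic calibration curves with 1/Y^2 weighting, extracts
    linear-dynamic-range slopes, builds and analytically inverts a
    polyQ-length calibration with delta-method error propagation, and
    computes accuracy/precision metrics (%RE, Cv) for validation mixtures.
    A companion algorithm computes average CAG repeat length from
    fragment-analysis peak traces (per-allele 5% height threshold,
    height-weighted mean, allele averaging), so protein-level and DNA-level
    measures of somatic repeat instability can be correlated. Includes a
    synthetic-data generator for standard curves, mixture signals, peak
    traces and paired protein/DNA cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
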