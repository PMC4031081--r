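Package: hormonet
Title: Lagged Cross-Correlation Network Inference for Pulsatile Hormone
    Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting lagged regulatory relations between
    hormones from densely sampled 24-hour cohort time series. Provides a
    simulator of coupled pulsatile secretion with exponential clearance,
    sparse non-negative deconvolution of concentration profiles into
    secretion profiles, per-subject lagged Pearson cross-correlation,
    cohort-level dynamic network inference with leave-two-out robustness
    and directionality validation, static and partial-correlation
    association networks, and paired treatment-effect testing with false
    discovery rate control. Networks are exported as edge tables and
    GraphML documents.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rlang,
    stats,
    utils,
    withr,
    xml2,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
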