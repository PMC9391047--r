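Package: causalts
Title: Causal-Discovery Diagnostics for Observational Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probing what pairwise-correlation surrogate tests,
    Granger causality, and state-space-reconstruction methods (convergent
    cross mapping) do and do not establish about causal structure in
    observational time series. Ships simulators for a family of toy
    ecological systems with separable process and measurement noise,
    surrogate-data dependence tests (permutation, phase randomization,
    time shift, cross-trial), linear Granger tests with a stationarity
    screen and a binned transfer-entropy variant, a full convergent
    cross-mapping pipeline with the four causality criteria, and
    benchmark drivers that tally false-positive rates and five-way
    inference outcomes over noise grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
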