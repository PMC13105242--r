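Package: dynsoar
Title: Transport-Effort Frontiers and a Reduced Optimal-Control Benchmark
    for Dynamic Soaring Flight
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for placing bird GPS/accelerometry trajectories on a common
    transport-effort plane and comparing them against a reduced optimal-control
    lower bound for wind-shear soaring. Continuous tracks are partitioned into
    overlapping windows; each window receives a ground-frame specific
    mechanical-energy budget with a quasi-steady drag term and an inferred
    atmospheric-input term, a net transport speed, and a mean vectorial dynamic
    body acceleration (VeDBA) effort proxy. Per-bird normalisation maps windows
    into dimensionless reduced speed-effort coordinates, binned lower-percentile
    frontiers summarise the best-observed trade-off, and the clipped bound
    Y(X) = max(0, a/X^2 + b*X^2 - W*X) is fitted to the soaring frontier by
    constrained multi-start least squares. A point-mass flight-dynamics
    simulator generates soaring, flap-gliding and continuously flapping cohorts
    with full energy bookkeeping so the whole pipeline is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    geosphere,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
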