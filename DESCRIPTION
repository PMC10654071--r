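Package: myxorun
Title: Cell-Run Statistics and Data-Driven Simulation of Myxococcus
    xanthus Aggregate Dispersal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying single-cell motility behavior during
    Myxococcus xanthus fruiting-body development and for simulating it back.
    Trajectories of tracked cells are coarse-grained into persistent and
    non-persistent runs delimited by reversals and state changes; each run is
    annotated with local density, nematic alignment, and nearest-aggregate
    covariates. From the resulting run database the package computes the
    reversal-bias statistic, traffic-jam metrics, bootstrap confidence
    intervals, and a logistic model of aggregate stability versus size.
    Fluorescence density movies are segmented with a globally rescaled Otsu
    threshold, aggregates are tracked and assigned stable/unstable fates, and
    the start of the coarsening phase is detected. A closed-loop, data-driven
    agent-based model resamples behavior from the run database via
    cue-matched nearest-neighbor search with kernel-density feedback,
    reproducing aggregate formation and size-dependent dispersal. A synthetic
    world generator with known ground-truth parameters makes the entire
    pipeline testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
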