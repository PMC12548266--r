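Package: adfluvial
Title: Classification of Adfluvial Fish Migratory Behaviors from Acoustic Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for characterizing migratory behavior of adfluvial,
    lake-dwelling fishes (developed for lake sturgeon, Acipenser fulvescens)
    from multi-year acoustic telemetry detection records.  Detection events
    are filtered (tag-collision min-lag rule, tag life, maturity, detection
    history span, spawning evidence, timeframe coverage), converted to daily
    habitat- and region-level state sequences by last-observation-carried-
    forward imputation, compared by optimal-matching edit distances under a
    geographic substitution-cost model, grouped by Ward agglomerative
    hierarchical clustering with average-silhouette-width model selection,
    and classified by a deterministic rule cascade into seven migratory
    behaviors (annual and intermittent spring river, intermittent two-step,
    river resident, annual summer river, annual winter river, annual
    interlake) with contingent route signatures, periodicity ratios, lake
    residency, frequency tables and sex-ratio goodness-of-fit tests.  A
    synthetic detection generator with known ground truth supports testing
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    cluster,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
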