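Package: circalum
Title: Circadian Rhythmometry for Bioluminescence Reporter Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of plate-luminometer bioluminescence recordings from
    circadian transcriptional reporters (e.g. luciferase reporters in
    C. elegans populations entrained to dual light/temperature cycles and
    then released into free run). Provides preprocessing of per-well
    luminescence traces (background subtraction, removal of the initial
    luciferase-accumulation transient, moving-average detrending and
    smoothing, normalization to the initial maximum), Lomb-Scargle period
    estimation on unevenly sampled series, cosinor fitting of MESOR,
    amplitude and acrophase with rhythmicity classification, circular
    statistics for acrophase distributions (mean phase, resultant length,
    Rayleigh test), relative qPCR quantification by the 2^-ddCt method with
    a from-scratch JTK_CYCLE rhythm test, and a seeded synthetic-data
    generator that emulates entrained/free-running plate recordings with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
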