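Package: navbouts
Title: Segmentation and Straightness Analysis of Animal GPS Tracks
Version: 0.1.0
Authors@R:
    person("Mondika", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing goal-directed navigation in ranging animals
    from interval-sampled GPS tracks and synchronous behavioural scans.
    Provides track projection and denoising, segmentation of daily paths into
    movement bouts (between successive feeding sites, or by greedy extension
    of consecutive-fix windows on directed long-distance days), path
    straightness and its backward evolution towards a target with loess
    smoothing, NOAA solar-position computation for sun-elevation covariates,
    maximum-likelihood beta regression of adjusted straightness with logit
    link and constant precision (with likelihood-ratio tests and marginal
    means), feeding-composition tables with Morisita-Horn similarity, and a
    synthetic-data module generating correlated and biased random-walk days,
    behavioural scans and regression datasets with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vegan
Config/testthat/edition: 3
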