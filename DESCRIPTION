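Package: openfieldr
Title: Analysis of Open Field Exploration Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing single-animal open field exploration
    experiments in circular arenas from raw tracking coordinates.
    Computes activity, boundary-sector coverage and its rescalings
    (percent coverage, PICA, PGCA), and turn-conditioned motion
    probabilities quantifying directional persistence; fits
    interpretable parametric habituation models per individual and per
    group with an outlier-robust two-pass bounded least-squares scheme;
    and compares experimental groups through a MANOVA, MANOVA sub-test,
    ANOVA and pairwise t-test ladder.  Includes readers for common
    tracker export dialects, a synthetic-track simulator with known
    ground truth, plotting of trajectories, individual and group-level
    relationships, and CSV export at every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
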