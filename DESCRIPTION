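Package: cetatrack
Title: Satellite-Track Reconstruction, Segmentation and Migration
    Bioenergetics for Cetaceans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for single-animal Argos satellite telemetry of
    migrating whales: speed/distance/angle pre-filtering of raw Argos fixes,
    track reconstruction with a continuous-time correlated random walk
    state-space model under per-fix error-ellipse observation error,
    time-varying movement-persistence estimation, penalized-contrast
    (Lavielle) change-point segmentation of migration phases and of the
    calving event, ocean-surface-current correction of swim speeds, a
    drag-based bioenergetic budget (Kleiber maintenance plus cubic
    cost-of-transport), and least-cost migration distances through water.
    Includes a synthetic-deployment generator with known ground truth so the
    full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    igraph,
    jsonlite,
    yaml,
    Matrix,
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
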