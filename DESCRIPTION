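Package: surgnav
Title: Markerless Surface-Based Registration for Image-Guided Neurosurgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for markerless, surface-based surgical navigation research:
    procedural digital head phantoms with conical measurement fiducials and
    planned biopsy trajectories; skin-surface extraction from volumetric head
    scans (threshold segmentation, median smoothing, solidification,
    iso-surfacing, quadric decimation, reference-model cropping); a depth-sensor
    simulator (pinhole depth rendering, point-cloud conversion, time-of-flight
    noise); fully automatic rigid registration of the reference surface to a
    live depth point cloud via feature-based robust global alignment (truncated
    least squares solved by graduated non-convexity, maximal-clique inlier
    pruning) followed by iterative-closest-point refinement; and an evaluation
    harness that measures navigation error with the off-plan-distance metric
    across controlled registration accuracies, head regions and simulated skin
    shift.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
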