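Package: arenatrack
Title: Rodent Arena Video Tracking and Trajectory Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tracks up to four rodents (one per arena) in behavior videos by
    background subtraction, computes the standard open-field and
    light-dark-box metrics (distance, per-zone time, mean speed,
    transitions, occupancy heatmaps) after pixel-to-centimeter calibration,
    and clusters subjects by their trajectories or heading-angle series
    using dynamic time warping dissimilarities with silhouette-guided
    k-means on a multidimensional-scaling embedding, or hierarchical
    agglomeration with five linkage methods. Includes a ground-truthed
    synthetic scene renderer so every stage of the pipeline can be
    exercised without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    EBImage,
    tiff,
    yaml,
    cluster,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
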