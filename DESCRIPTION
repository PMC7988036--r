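Package: fourrooms
Title: Place-Cell Connectivity-Coding Analyses for a Four-Room Maze
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for hippocampal CA1 place-cell recordings in a
    four-room maze whose rooms are joined by lockable saloon doors. Implements
    the maze connectivity model (directed door graph, shortest door paths,
    quadrant assignment), segmentation of behavior into foraging and
    goal-directed epochs with connectivity-knowledge metrics,
    occupancy-normalized Gaussian-smoothed firing rate maps with Skaggs
    spatial information and spike-shift shuffles, place-field detection with
    a doorway bridge index and overrepresentation tests, correlation- and
    rate-based remapping analyses with random-cell shuffle nulls, memoryless
    Poisson Bayesian decoding of box quadrants, cluster-quality metrics
    (isolation distance, L-ratio), and an inhomogeneous-Poisson simulator
    that generates session sequences with known ground truth so every stage
    has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    cluster
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
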