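Package: hexnav
Title: Graph-Based Trajectory Analysis and Generative Modelling of Rodent
    HexMaze Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying rodent goal-localization behavior on the
    HexMaze, a modular arena of six hexagonal corridors around a central
    hexagonal circuit (24 intersection nodes, 30 gangways). Trajectories are
    represented as node sequences on the maze graph and summarized by the
    relative trial length (RTL), distance-from-optimal-path (DFOP) profiles,
    maximal stray, and inner/outer-ring occupancy. DFOP profiles are
    parametrized by a normalized difference-of-Gaussians fit, and a minimal
    two-parameter generative navigation model (diagonal-run probability eta
    and goal foresight F) is fitted to observed trial groups by minimizing
    the two-sample Kolmogorov-Smirnov distance between simulated and
    observed RTL distributions. A synthetic-protocol generator emulates the
    experimental start/goal constraints so that learning-induced strategy
    shifts can be simulated and recovered end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
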