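Package: exna
Title: Excitable Network Attractors in Continuous-Time Recurrent Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Constructs continuous-time recurrent neural networks (CTRNNs)
    whose input-free dynamics realise an arbitrary admissible directed graph
    as an excitable network attractor: one stable equilibrium per graph
    vertex, joined by excitable connections along the graph edges. Provides
    graph admissibility validation (no self-loops, two-cycles or
    delta-cliques), the four-weight coupling-matrix synthesis and its
    parameter recipe, deterministic and stochastic (Euler-Maruyama)
    simulation, Newton refinement of equilibria with stability analysis,
    saddle-node and SNIC bifurcation threshold detection, symbolic itinerary
    extraction from trajectories, and execution of finite-state walks on the
    network driven by input pulses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
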