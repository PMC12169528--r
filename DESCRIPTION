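Package: misinfluence
Title: Centrality Metrics and Intervention Simulation for Health
    Misinformation Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying influential and vulnerable accounts in
    directed interaction networks that spread health misinformation.
    Implements three propagation-aware centrality metrics -- propagation
    centrality (a damped, out-degree-normalised steady-state score),
    misinformation vulnerability centrality (degree-amplified
    susceptibility), and dynamic influence centrality (cumulative
    in-neighbour influence over discrete timesteps) -- alongside the four
    classical baselines (degree, closeness with a harmonic fallback,
    betweenness, eigenvector with a teleport perturbation). Includes top-k
    overlap partitioning and coverage-gain analysis, proxy-ground-truth
    rank alignment, an independent-cascade node-removal intervention
    simulator, and seeded generators for retweet-style synthetic networks
    with planted hubs, vulnerable amplifiers, and persistent spreaders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
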