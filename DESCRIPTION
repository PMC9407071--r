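Package: tscomplexity
Title: Complexity Indices for Time Series and the Latent Structure of Index Batteries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation of benchmark signals (random walks, oscillators,
    Lorenz attractors, EEG-like surrogates) degraded by colored (1/f)^beta
    noise over a factorial grid, computation of a battery of complexity
    indices (permutation-entropy family, multifractal detrended fluctuation
    analysis features, Hjorth parameters, singular-value-decomposition
    entropy, attention entropy, and a set of classical entropy and fractal
    dimension measures), and analysis of the latent structure of the battery
    through correlation, factor analysis with varimax rotation, hierarchical
    clustering and greedy variance-explained index selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    deSolve,
    MASS,
    yaml,
    parallel
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
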