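Package: chronconn
Title: Reliability of Static and Dynamic Source-Space Functional
    Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for band-limited source-space functional connectivity
    analysis and its test-retest reliability. Builds static and
    sliding-window dynamic connectivity graphs from multichannel
    region-of-interest time series with the imaginary phase-locking value
    and the orthogonalized amplitude-envelope correlation, filters them
    statistically (single-cut surrogates with Benjamini-Hochberg FDR) and
    topologically (orthogonal minimal spanning trees maximizing global
    efficiency minus cost), computes nodal graph metrics, graph diffusion
    distances and multidimensional-scaling projections, reduces dynamic
    graph sequences to functional-connectivity microstates via Laplacian
    eigenspectra and neural-gas vector quantization, and summarizes the
    resulting symbolic state sequences with chronnectomic statistics
    (transition rate, occupancy times, transition-probability matrices)
    whose across-session reliability is assessed over a cohort. Includes a
    synthetic two-session cohort generator with planted coupling structure
    and planted Markovian state switching, so every stage of the pipeline
    can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
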