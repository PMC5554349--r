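Package: netvis3d
Title: Headless 3D Layout, Clustering and Rendering of Biomolecular Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Three-dimensional network visualization engine for biomolecular
    interaction data, usable entirely from scripts (no display required).
    Provides seven 3D layout algorithms (force-directed, node- and
    edge-repulsion lin-log, spectral hybrid, multilevel coarsened, simulated
    annealing with edge cutting, semantic z-levels, and a degree-ranked
    hemispherical layout), graph clustering (budgeted edge-betweenness sweeps,
    Markov clustering, leading-eigenvector modularity), cluster bubble and 3D
    Circos layouts, force-directed 3D edge bundling, network topology
    statistics with rank-ordered tables, seeded synthetic network generators,
    and a deterministic software renderer producing PNG snapshots and rotating
    GIF movies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    jsonlite,
    png,
    Rcpp,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
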