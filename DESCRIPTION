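Package: mstmap
Title: Tree Maps of Large High-Dimensional Data via MinHash, LSH Forests
    and Minimum Spanning Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Visualizes large high-dimensional binary-set and non-negative
    weighted data as trees on the Euclidean plane.  Records are sketched
    with MinHash (or Ioffe-style consistent weighted sampling for weighted
    vectors), indexed in an LSH forest of prefix trees, connected into a
    c-approximate k-nearest-neighbor graph weighted by estimated Jaccard
    distance, reduced to a minimum spanning forest with Kruskal's
    algorithm, and laid out with a deterministic multilevel
    spring-electrical model using Barnes-Hut quadtree force approximation.
    Includes a clustered synthetic-data generator with analytic ground
    truth, locality-preservation diagnostics, and delimited-text/GraphML
    import and export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    vegan,
    xml2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
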