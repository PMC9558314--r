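Package: gridtopo
Title: Graph-Based Topological Analysis of Scalar Fields on Arbitrary Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Topological and topographical analysis of a scalar field known
    only by its values on an arbitrary set of points, strictly by
    post-processing and with no additional function evaluations. Points are
    connected into a neighborhood graph (Delaunay triangulation or
    k-nearest-neighbor), on which the package identifies local maxima and
    spatially extended maxima families, assigns every point to a basin of
    attraction by on-graph steepest ascent or by a bias-corrected off-graph
    ascent, integrates per-basin quantities (Bader charges), and extracts
    critical networks (maximum-spanning-tree critical paths, bond critical
    points, gap-filled cycles, cleaved subtrees). Field transforms extend the
    same machinery to minima, isosurfaces, shell structure of the density
    Laplacian, and stagnation graphs of current densities. Includes synthetic
    model fields and grids with known topology, Gaussian cube and tabular
    point-file input/output, a command-line interface, and a compact
    restricted Hartree-Fock engine used to generate benchmark electron
    densities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    RANN,
    reticulate,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deldir
Config/testthat/edition: 3
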