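Package: qclique
Title: Maximum Quasi-Clique Detection and Dense Percolation in Random
    Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detection and analysis of gamma-quasi-cliques (dense modules)
    in undirected networks such as protein interaction graphs.  Provides
    exact maximum quasi-clique solvers (combinatorial branch-and-bound,
    a mixed-integer linear programming formulation with a pluggable
    backend, and a brute-force oracle), a GRASP heuristic for moderate
    graphs, first-moment analytics (expected quasi-clique counts,
    critical sizes, asymptotic size bounds, Chernoff and normal-tail
    estimators of binomial tails), and Erdos-Renyi G(n,p) sweep
    experiments exhibiting the first-order dense percolation transition.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
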