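test_that("required edge counts use exact ceiling arithmetic", {
  expect_equal(required_edges(4, "0.85"), 6)   # ceil(5.1)
  expect_equal(required_edges(5, "0.85"), 9)   # ceil(8.5)
  expect_equal(required_edges(3, "0.9"), 3)    # ceil(2.7)
  expect_equal(required_edges(1, "0.5"), 0)
  # integer product where double ceiling(0.7 * 210) would give 148
  expect_equal(required_edges(21, "0.7"), 147)
  expect_error(required_edges(4, "0"), "gamma")
})

test_that("the pass/fail boundary is exact for all k up to 1000", {
  # the decision must flip exactly between req - 1 and req edges; check
  # against an integer-cleared inequality computed independently
  for (gam in c("0.85", "0.9", "0.7", "0.333")) {
    r <- qc_rational(gam)
    k <- 1:1000
    req <- required_edges(k, gam)
    # 2*b*e >= a*k*(k-1) iff e >= req  (integers below 2^53 throughout)
    expect_true(all(2 * r$den * req >= r$num * k * (k - 1)))
    expect_true(all(2 * r$den * (req - 1) < r$num * k * (k - 1) |
                      req == 0))
  }
})

test_that("edge density and gamma membership match direct counting", {
  expect_equal(edge_density(complete_graph(3), c("a", "b", "c")), 1)
  two <- edgeless_graph(2)
  expect_equal(edge_density(two, c("a", "b")), 0)
  expect_equal(edge_density(two, "a"), 1)  # size-1 convention

  minus_one_edge <- function(k) {       # K_k with the first pair removed
    pairs <- t(utils::combn(glabels(k), 2))[-1, ]
    qc_graph(pairs, labels = glabels(k))
  }
  g5 <- minus_one_edge(4)
  expect_equal(edge_density(g5, letters[1:4]), 5 / 6)

  s <- qc_spec("0.85")
  expect_true(is_gamma_quasi_clique(complete_graph(3), letters[1:3], s))
  expect_false(is_gamma_quasi_clique(g5, letters[1:4], s))  # 5 < 6
  # 5 vertices, 9 internal edges: exactly at the ceil(8.5) boundary
  k5m <- minus_one_edge(5)
  expect_equal(qclique:::edges_within(k5m, 1:5), 9)
  expect_true(is_gamma_quasi_clique(k5m, 1:5, s))

  expect_error(edge_density(two, character(0)), "empty")
  expect_error(edge_density(two, "zz"), "unknown")
})

test_that("connectivity flag implements the connected variant", {
  # two disjoint edges on 4 vertices: 2 of 6 pairs, so gamma = 0.3
  # passes on density (ceil(1.8) = 2) but fails connectivity
  two_edges <- qc_graph(cbind(c("a", "c"), c("b", "d")))
  s <- qc_spec("0.3")
  sc <- qc_spec("0.3", connected = TRUE)
  expect_true(is_gamma_quasi_clique(two_edges, letters[1:4], s))
  expect_false(is_gamma_quasi_clique(two_edges, letters[1:4], sc))
})

test_that("(lambda,gamma) membership checks degrees and density", {
  expect_true(is_lambda_gamma_quasi_clique(
    complete_graph(5), letters[1:5], qc_spec("0.9", lambda = "0.9")))
  # 5-cycle: each degree 2 >= ceil(0.5*4) = 2, edges 5 >= ceil(5) = 5
  expect_true(is_lambda_gamma_quasi_clique(
    cycle_graph(5), letters[1:5], qc_spec("0.5", lambda = "0.5")))
  # star on 5: leaves have degree 1 < 2
  expect_false(is_lambda_gamma_quasi_clique(
    star_graph(5), letters[1:5], qc_spec("0.4", lambda = "0.5")))
})

test_that("any (lambda,gamma) pass implies the gamma-only pass", {
  set.seed(31)
  spec_lg <- qc_spec("0.6", lambda = "0.5")
  spec_g <- qc_spec("0.6")
  hits <- 0
  for (i in 1:40) {
    g <- sample_gnp(20, 0.6, seed = 1000 + i)
    sub <- sample.int(20, sample(3:8, 1))
    if (is_lambda_gamma_quasi_clique(g, sub, spec_lg)) {
      hits <- hits + 1
      expect_true(is_gamma_quasi_clique(g, sub, spec_g))
    }
  }
  expect_gt(hits, 0)
})

test_that("cliques pass for every gamma (monotonicity)", {
  k6 <- complete_graph(6)
  for (gam in c("0.2", "0.5", "0.85", "1"))
    expect_true(is_gamma_quasi_clique(k6, letters[1:6], qc_spec(gam)))
})

test_that("subset diameter distinguishes cliques, paths and split sets", {
  expect_equal(subset_diameter(complete_graph(4), letters[1:4]), 1)
  expect_equal(subset_diameter(path_graph(3), letters[1:3]), 2)
  expect_equal(subset_diameter(qc_graph(cbind(c("a", "c"), c("b", "d"))),
                               letters[1:4]), Inf)
  expect_equal(subset_diameter(complete_graph(3), "a"), 0)
})

test_that("dense cores with lambda >= 1/2 have diameter at most 2", {
  spec <- qc_spec("0.5", lambda = "0.5")
  checked <- 0
  for (i in 1:60) {
    g <- sample_gnp(24, 0.55, seed = 2000 + i)
    sub <- withr::with_seed(i, sample.int(24, sample(4:9, 1)))
    if (is_lambda_gamma_quasi_clique(g, sub, spec)) {
      checked <- checked + 1
      expect_lte(subset_diameter(g, sub), 2)
    }
  }
  expect_gt(checked, 5)  # the property was actually exercised
})
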