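test_that("brute force solves the canonical small cases", {
  expect_equal(max_quasi_clique_bruteforce(complete_graph(5),
                                           qc_spec("0.9"))$size, 5)
  expect_equal(max_quasi_clique_bruteforce(edgeless_graph(6),
                                           qc_spec("0.5"))$size, 1)
  expect_equal(max_quasi_clique_bruteforce(cycle_graph(5),
                                           qc_spec("0.5"))$size, 5)
  expect_equal(max_quasi_clique_bruteforce(cycle_graph(5),
                                           qc_spec("0.6"))$size, 3)
  expect_error(max_quasi_clique_bruteforce(sample_gnp(25, 0.2, seed = 1),
                                           qc_spec("0.85")), "k_cap")
})

test_that("brute force reports the lexicographically smallest optimum", {
  # two disjoint triangles; {a,b,c} and {d,e,f} are both optimal
  g <- qc_graph(cbind(c("d", "e", "f", "a", "b", "c"),
                      c("e", "f", "d", "b", "c", "a")))
  res <- max_quasi_clique_bruteforce(g, qc_spec("0.9"))
  expect_equal(res$vertices, c("a", "b", "c"))
})

test_that("branch and bound agrees with enumeration across random instances", {
  cases <- expand.grid(p = c(0.2, 0.5, 0.8),
                       gamma = c("0.6", "0.85", "0.9"),
                       rep = 1:6, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    g <- sample_gnp(12, cases$p[i], seed = 5000 + i)
    spec <- qc_spec(cases$gamma[i])
    bs <- max_quasi_clique_bruteforce(g, spec)
    es <- max_quasi_clique_exact(g, spec)
    expect_equal(es$size, bs$size,
                 info = sprintf("p=%s gamma=%s rep=%d", cases$p[i],
                                cases$gamma[i], cases$rep[i]))
    expect_true(es$is_optimal)
  }
})

test_that("exact solver recovers planted dense subsets and cliques", {
  pl <- plant_dense_subset(60, 0.1, 10, "0.9", seed = 17)
  res <- max_quasi_clique_exact(pl$graph, qc_spec("0.9"))
  expect_gte(res$size, 10)
  expect_true(res$is_optimal)
  for (gam in c("0.5", "0.85", "1"))
    expect_equal(max_quasi_clique_exact(complete_graph(8),
                                        qc_spec(gam))$size, 8)
})

test_that("solutions are verified quasi-cliques and sizes are monotone in gamma", {
  g <- sample_gnp(40, 0.3, seed = 23)
  sizes <- vapply(c("0.5", "0.7", "0.85", "0.95", "1"), function(gam) {
    r <- max_quasi_clique_exact(g, qc_spec(gam))
    expect_true(is_gamma_quasi_clique(g, r$vertices, qc_spec(gam)))
    r$size
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("feasible sizes form a prefix (quasi-heredity)", {
  # existence of a size-k quasi-clique implies existence at size k-1;
  # oracle: plain combn enumeration, independent of the C++ engines
  for (i in 1:12) {
    g <- sample_gnp(11, c(0.3, 0.5, 0.7)[1 + i %% 3], seed = 7000 + i)
    for (gam in c("0.6", "0.85")) {
      feas <- feasible_sizes_oracle(g, gam)
      kmax <- max(which(feas))
      expect_equal(which(feas), seq_len(kmax),
                   info = sprintf("instance %d gamma %s", i, gam))
      # and the B&B answer matches the oracle's maximum
      expect_equal(max_quasi_clique_exact(g, qc_spec(gam))$size, kmax)
    }
  }
})

test_that("node budget returns an incumbent without an optimality claim", {
  g <- sample_gnp(40, 0.5, seed = 3)
  expect_warning(res <- max_quasi_clique_exact(g, qc_spec("0.6"),
                                               max_nodes = 50),
                 "budget")
  expect_false(res$is_optimal)
  expect_true(is_gamma_quasi_clique(g, res$vertices, qc_spec("0.6")))
})

test_that("solver engines reject lambda/connected specifications", {
  g <- complete_graph(4)
  expect_error(max_quasi_clique_exact(g, qc_spec("0.85", lambda = "0.5")),
               "gamma-density")
  expect_error(max_quasi_clique_bruteforce(g, qc_spec("0.85",
                                                      connected = TRUE)),
               "gamma-density")
})
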