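test_that("Bernoulli KL divergence hits its closed-form anchors", {
  expect_equal(kl_bernoulli(1, 0.5), log(2))
  expect_equal(kl_bernoulli(0.3, 0.3), 0)
  expect_equal(kl_bernoulli(0.85, 0.05), 2.1313, tolerance = 1e-3)
  expect_error(kl_bernoulli(0.5, 0), "\\(0, 1\\)")
  expect_error(kl_bernoulli(0.5, 1), "\\(0, 1\\)")
})

test_that("size bounds are ordered, collapse at gamma = 1, and reject p >= gamma", {
  b <- quasi_clique_size_bounds(100, 0.05, "0.85")
  expect_lt(b["lower"], b["upper"])
  b1 <- quasi_clique_size_bounds(1000, 0.3, "1")
  expect_equal(unname(b1["lower"]), unname(b1["upper"]))
  expect_error(quasi_clique_size_bounds(100, 0.9, "0.85"), "dense phase")
  # for all p < gamma, ln(1/p) >= D(gamma||p): lower <= upper
  for (p in seq(0.05, 0.8, by = 0.05))
    for (gam in c(0.85, 0.9, 0.95))
      if (p < gam) {
        b <- quasi_clique_size_bounds(200, p, gam)
        expect_lte(b[["lower"]], b[["upper"]])
      }
})

test_that("binomial upper tails match exact-rational summation", {
  # expected values computed by exact rational summation (integer
  # binomials over fractional p), then frozen
  expect_equal(binom_tail_exact(10, 0.5, 5), 0.623046875)
  expect_equal(binom_tail_exact(20, 0.2, 8), 0.03214266308087513)
  expect_equal(binom_tail_exact(64, 0.25, 30), 1.2300744423127813e-04)
  expect_equal(binom_tail_exact(6, 0.2, 6), 6.4e-05)
  expect_equal(binom_tail_exact(30, 0.3, 17), 0.0021246907506543124)
  expect_equal(binom_tail_exact(12, 0.3, 0), 1)
  expect_equal(binom_tail_exact(12, 0.3, 13), 0)
})

test_that("expected quasi-clique counts evaluate eq-style closed forms", {
  expect_equal(expected_quasi_clique_count(10, 0.1, "0.5", 2), 4.5)
  # C(20,4) * P[Bin(6,0.2) >= 6] = 4845 * 0.2^6
  expect_equal(expected_quasi_clique_count(20, 0.2, "0.85", 4),
               0.310080, tolerance = 1e-9)
  # monotone in p at fixed (n, k, gamma)
  e <- vapply(c(0.1, 0.2, 0.3, 0.4),
              function(p) expected_quasi_clique_count(30, p, "0.85", 5),
              numeric(1))
  expect_true(all(diff(e) > 0))
})

test_that("critical size k* brackets the unit expected count", {
  expect_equal(critical_size_k_star(100, 0.5, "1"), 9)
  ks <- critical_size_k_star(80, 0.2, "0.85")
  expect_gte(expected_quasi_clique_count(80, 0.2, "0.85", ks), 1)
  expect_lt(expected_quasi_clique_count(80, 0.2, "0.85", ks + 1), 1)
  # k* >= 2 whenever E[Y_2] = C(n,2) p >= 1
  expect_gte(critical_size_k_star(30, 0.1, "0.9"), 2)
  # main asymptotic term: k* ~ 2 ln n / D(gamma||p); the o(log n)
  # corrections are still sizeable at n = 1e6 (ln k / ln n ~ 0.3), so
  # check the frozen exact value and the monotone approach of the ratio
  # toward 1 as n grows
  expect_equal(critical_size_k_star(1e6, 0.5, "0.9"), 58)
  ratios <- vapply(c(1e6, 1e9, 1e12), function(n)
    critical_size_k_star(n, 0.5, "0.9") /
      (2 * log(n) / kl_bernoulli(0.9, 0.5)), numeric(1))
  expect_true(all(diff(ratios) > 0))
  expect_true(all(ratios > 0.5 & ratios < 1))
})

test_that("the Chernoff bound dominates exact tails and is tight at gamma = 1", {
  expect_equal(chernoff_tail_bound(6, 0.2, 1), 0.2^6)
  expect_equal(chernoff_tail_bound(15, 0.4, 0.4), 1)
  for (m in 1:30)
    for (p in seq(0.1, 0.9, by = 0.1))
      for (gam in seq(p + 0.1, 1, by = 0.1))
        expect_gte(chernoff_tail_bound(m, p, gam) + 1e-15,
                   binom_tail_exact(m, p, ceiling(gam * m)))
})

test_that("the normal-tail estimate tracks exact tails and improves with m", {
  relerr <- function(m, k) {
    ex <- binom_tail_exact(m, 0.3, k)
    abs(mckay_tail_approx(m, 0.3, k) / ex - 1)
  }
  expect_lt(relerr(100, 45), 0.10)
  expect_lt(relerr(400, 150), 0.05)
  # fixed standardized deviation, m growing: error shrinks
  errs <- vapply(c(100, 400, 1600),
                 function(m) relerr(m, round(0.45 * m)), numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_error(mckay_tail_approx(100, 0.3, 20), "regime")
})

test_that("bound reports assemble consistent pieces", {
  rep <- bound_report(100, 0.05, "0.85")
  expect_s3_class(rep, "qc_bound_report")
  expect_equal(rep$k_star, critical_size_k_star(100, 0.05, "0.85"))
  expect_gte(rep$e_counts[[as.character(rep$k_star)]], 1)
  expect_lte(rep$lower, rep$upper)
})
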