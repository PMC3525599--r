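# First-moment analytics for gamma-quasi-cliques in G(n,p).
#
# The expected number of gamma-quasi-cliques of size k is
#   E[Y_k] = C(n,k) * P[ Bin(C(k,2), p) >= required_edges(k, gamma) ],
# and the critical size k* where E[Y_k] crosses 1 carries the main
# asymptotic term 2 ln n / D(gamma||p), with D the Bernoulli
# Kullback-Leibler divergence.  These quantities drive both the
# size bounds on the maximum quasi-clique and the analysis of the dense
# percolation transition.

#' Bernoulli Kullback-Leibler divergence D(gamma || p)
#'
#' `gamma*log(gamma/p) + (1-gamma)*log((1-gamma)/(1-p))`, with the
#' clique limit `log(1/p)` at `gamma = 1`.  This divergence is the decay
#' rate of the binomial tail `P[Bin(m,p) >= gamma*m]` and the
#' denominator of the asymptotic quasi-clique size bound.
#'
#' @param gamma reference density in (0, 1\].
#' @param p edge probability, strictly inside (0, 1).
#' @return a nonnegative numeric.
#' @examples
#' kl_bernoulli(1, 0.5)     # log(2)
#' kl_bernoulli(0.85, 0.05)
#' @export
kl_bernoulli <- function(gamma, p) {
  gamma <- if (inherits(gamma, "qc_rational")) gamma$value else gamma
  if (p <= 0 || p >= 1) stop("`p` must lie strictly inside (0, 1)")
  if (gamma <= 0 || gamma > 1) stop("`gamma` must lie in (0, 1]")
  if (gamma == 1) return(log(1 / p))
  gamma * log(gamma / p) + (1 - gamma) * log((1 - gamma) / (1 - p))
}

#' Asymptotic size bounds for the maximum quasi-clique in G(n,p)
#'
#' For `p < gamma` the size of the maximum gamma-quasi-clique in a
#' uniform random graph is (asymptotically, almost surely) between
#' `2*log(n)/log(1/p)` -- the maximum clique plug-in -- and
#' `2*log(n)/D(gamma||p)`.  The two coincide at `gamma = 1`.
#'
#' @param n number of vertices (>= 2).
#' @param p edge probability with `0 < p < gamma`.
#' @param gamma density threshold in (0, 1\].
#' @return named numeric `c(lower, upper)`, in vertices.
#' @examples
#' quasi_clique_size_bounds(100, 0.05, "0.85")  # c(3.07..., 4.32...)
#' @export
quasi_clique_size_bounds <- function(n, p, gamma) {
  gamma <- qc_rational(gamma)
  stopifnot(n >= 2)
  if (p <= 0 || p >= 1) stop("`p` must lie strictly inside (0, 1)")
  if (p >= gamma$value)
    stop("`p` >= `gamma`: dense phase, the whole graph is w.h.p. a ",
         "quasi-clique and the logarithmic bound does not apply")
  c(lower = 2 * log(n) / log(1 / p),
    upper = 2 * log(n) / kl_bernoulli(gamma, p))
}

#' Upper tail of the binomial distribution
#'
#' `P[Bin(m, p) >= k]`, computed through the (log-space capable)
#' distribution function.  Returns 1 for `k <= 0` and 0 for `k > m`.
#'
#' @param m number of trials.
#' @param p success probability.
#' @param k threshold count.
#' @param log.p return the log probability?
#' @return a probability (or its log).
#' @examples
#' binom_tail_exact(10, 0.5, 5)  # 0.623046875
#' @export
binom_tail_exact <- function(m, p, k, log.p = FALSE) {
  stopifnot(m >= 0)
  if (k > m) return(if (log.p) -Inf else 0)
  if (k <= 0) return(if (log.p) 0 else 1)
  pbinom(k - 1, m, p, lower.tail = FALSE, log.p = log.p)
}

#' Expected number of gamma-quasi-cliques of size k in G(n,p)
#'
#' `choose(n,k) * P[Bin(k(k-1)/2, p) >= required_edges(k, gamma)]`,
#' evaluated in log space so that large `n` does not overflow.
#'
#' @param n,p Erdos-Renyi parameters.
#' @param gamma density threshold in (0, 1\].
#' @param k subset size, `2 <= k <= n`.
#' @return a nonnegative expected count.
#' @examples
#' expected_quasi_clique_count(10, 0.1, "0.5", 2)  # choose(10,2)*0.1 = 4.5
#' @export
expected_quasi_clique_count <- function(n, p, gamma, k) {
  stopifnot(k >= 2, k <= n)
  gamma <- qc_rational(gamma)
  r <- required_edges(k, gamma)
  exp(lchoose(n, k) +
        binom_tail_exact(k * (k - 1) / 2, p, r, log.p = TRUE))
}

#' Critical quasi-clique size k*
#'
#' The largest `k` with `E[Y_k] >= 1` (ascending integer scan from
#' `k = 2`); `E[Y_k] = 1` generically falls between integers and this
#' integerization is the package's convention.  Asymptotically
#' `k* ~ 2*log(n)/D(gamma||p)`.
#'
#' @inheritParams expected_quasi_clique_count
#' @return an integer size, at least 1.
#' @examples
#' critical_size_k_star(100, 0.5, 1)  # 9: E[Y_9] ~ 27.7, E[Y_10] ~ 0.49
#' @export
critical_size_k_star <- function(n, p, gamma) {
  stopifnot(n >= 2)
  gamma <- qc_rational(gamma)
  if (p <= 0 || p >= 1) stop("`p` must lie strictly inside (0, 1)")
  if (p >= gamma$value) stop("`p` >= `gamma`: dense phase")
  kstar <- 1L
  for (k in 2:n) {
    if (expected_quasi_clique_count(n, p, gamma, k) >= 1) kstar <- k
    else break
  }
  kstar
}

#' Chernoff (relative-entropy) bound on the binomial upper tail
#'
#' `P[Bin(m, p) >= gamma*m] <= exp(-m * D(gamma||p))` for
#' `gamma > p`; the bound is vacuous (1) otherwise.  At `gamma = 1` it
#' coincides with the exact tail `p^m`.
#'
#' @param m number of trials.
#' @param p success probability in (0, 1).
#' @param gamma tail fraction in (0, 1\].
#' @return an upper bound on the tail probability.
#' @export
chernoff_tail_bound <- function(m, p, gamma) {
  gamma <- if (inherits(gamma, "qc_rational")) gamma$value else gamma
  if (gamma <= p) return(1)
  exp(-m * kl_bernoulli(gamma, p))
}

#' Normal-based large-deviation estimate of the binomial upper tail
#'
#' McKay-style refinement of the normal approximation for
#' `P[Bin(m, p) >= k]` in the large-deviation regime `k > m*p`:
#' with `g = k/m`, `D = D(g||p)` and `y = sqrt(2*m*D)`,
#' `P ~ c(g, p) * (1 - Phi(y))` where
#' `c = g*(1-p)*sqrt(2*D) / ((g-p)*sqrt(g*(1-g)))` and `Phi` is the
#' standard normal distribution function.  This is an estimate, not a
#' bound; its relative error shrinks as `m` grows at fixed standardized
#' deviation.  For `k = m` the exact tail `p^m` is returned.
#'
#' @param m number of trials.
#' @param p success probability in (0, 1).
#' @param k threshold count with `m*p < k <= m`.
#' @return an approximate tail probability.
#' @export
mckay_tail_approx <- function(m, p, k) {
  stopifnot(m >= 1, k <= m)
  if (p <= 0 || p >= 1) stop("`p` must lie strictly inside (0, 1)")
  if (k <= m * p)
    stop("approximation regime violated: need k > m*p")
  if (k == m) return(p^m)
  g <- k / m
  D <- kl_bernoulli(g, p)
  y <- sqrt(2 * m * D)
  cfac <- g * (1 - p) * sqrt(2 * D) / ((g - p) * sqrt(g * (1 - g)))
  cfac * pnorm(y, lower.tail = FALSE)
}

#' Analytic bound report for G(n,p) quasi-cliques
#'
#' Collects, for one `(n, p, gamma)`, the asymptotic lower/upper size
#' bounds, the critical size `k*`, and the table of expected counts
#' `E[Y_k]`.
#'
#' @inheritParams expected_quasi_clique_count
#' @param k_max largest size tabulated in `e_counts` (default
#'   `min(n, k* + 5)`).
#' @return an object of class `qc_bound_report`: a list with fields
#'   `n`, `p`, `gamma`, `lower`, `upper`, `k_star`, `e_counts`.
#' @export
bound_report <- function(n, p, gamma, k_max = NULL) {
  gamma <- qc_rational(gamma)
  b <- quasi_clique_size_bounds(n, p, gamma)
  ks <- critical_size_k_star(n, p, gamma)
  if (is.null(k_max)) k_max <- min(n, ks + 5L)
  kk <- 2:k_max
  ec <- vapply(kk, function(k)
    expected_quasi_clique_count(n, p, gamma, k), numeric(1))
  names(ec) <- kk
  structure(list(n = n, p = p, gamma = gamma,
                 lower = unname(b["lower"]), upper = unname(b["upper"]),
                 k_star = ks, e_counts = ec),
            class = "qc_bound_report")
}

#' @export
print.qc_bound_report <- function(x, ...) {
  cat(sprintf(
    "<qc_bound_report> n = %d, p = %g, gamma = %g\n  size bounds [%.2f, %.2f], k* = %d\n",
    x$n, x$p, x$gamma$value, x$lower, x$upper, x$k_star))
  invisible(x)
}
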