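# Quasi-clique membership predicates.
#
# A k-vertex subset S is a gamma-quasi-clique when its induced edge count
# is at least ceiling(gamma * k(k-1)/2).  All threshold comparisons are
# carried out in exact integer arithmetic after clearing denominators:
# "at least gamma" with integer edge counts forces the ceiling, and ties
# at exactly gamma * C(k,2) pass.

#' Quasi-clique requirement specification
#'
#' Bundles the edge-density threshold gamma, the optional degree
#' fraction lambda of the (lambda,gamma)-quasi-clique (gamma-core)
#' variant, and the connectivity flag.  The basic definition does not
#' require connectivity; `connected = TRUE` additionally demands a
#' connected induced subgraph.
#'
#' @param gamma edge-density threshold in (0, 1\], decimal string or
#'   numeric.
#' @param lambda optional degree fraction in \[0, 1\]: every member must
#'   have at least `ceiling(lambda * (k - 1))` neighbours inside the
#'   subset.
#' @param connected require the induced subgraph to be connected?
#' @return an object of class `qc_spec`.
#' @examples
#' qc_spec("0.85")
#' qc_spec("0.9", lambda = "0.5")
#' @export
qc_spec <- function(gamma, lambda = NULL, connected = FALSE) {
  gamma <- qc_rational(gamma)
  if (gamma$num <= 0 || gamma$num > gamma$den)
    stop("`gamma` must lie in (0, 1]")
  if (!is.null(lambda)) {
    lambda <- qc_rational(lambda)
    if (lambda$num > lambda$den) stop("`lambda` must lie in [0, 1]")
  }
  structure(list(gamma = gamma, lambda = lambda,
                 connected = isTRUE(connected)),
            class = "qc_spec")
}

#' @export
print.qc_spec <- function(x, ...) {
  cat(sprintf("<qc_spec> gamma = %g/%g%s%s\n", x$gamma$num, x$gamma$den,
              if (is.null(x$lambda)) "" else
                sprintf(", lambda = %g/%g", x$lambda$num, x$lambda$den),
              if (x$connected) ", connected" else ""))
  invisible(x)
}

#' Edges required for a dense cluster of a given size
#'
#' The number of links required for `k` nodes to form a gamma-dense
#' cluster: `ceiling(gamma * k * (k - 1) / 2)`, evaluated in exact
#' rational arithmetic.
#'
#' @param k cluster size (>= 1); vectorized.
#' @param gamma density threshold in (0, 1\], decimal string or numeric.
#' @return integer edge count(s); 0 for `k = 1`.
#' @examples
#' required_edges(4, "0.85")  # ceiling(5.1) = 6
#' required_edges(5, "0.85")  # ceiling(8.5) = 9
#' @export
required_edges <- function(k, gamma) {
  gamma <- qc_rational(gamma)
  if (gamma$num <= 0 || gamma$num > gamma$den)
    stop("`gamma` must lie in (0, 1]")
  stopifnot(all(k >= 1))
  vapply(k, function(kk) {
    tot <- gamma$num * kk * (kk - 1)
    den <- 2 * gamma$den
    tot %/% den + ((tot %% den) > 0)
  }, numeric(1))
}

# required internal edges for sizes 0..n, as passed to the C++ engines
required_edges_vector <- function(n, gamma)
  c(0, 0, required_edges(2:max(n, 2), gamma))[seq_len(n + 1)]

#' Edge density of an induced subgraph
#'
#' Internal edge count divided by `choose(k, 2)`; by convention 1 for a
#' single vertex.
#'
#' @param graph a [qc_graph()].
#' @param subset node labels or 1-based indices (nonempty).
#' @return a numeric density in \[0, 1\].
#' @export
edge_density <- function(graph, subset) {
  idx <- resolve_subset(graph, subset)
  k <- length(idx)
  if (k == 1L) return(1)
  edges_within(graph, idx) / (k * (k - 1) / 2)
}

subset_connected <- function(graph, idx) {
  if (length(idx) == 1L) return(TRUE)
  comp <- igraph::components(induced_igraph(graph, idx))
  comp$no == 1L
}

#' Test gamma-quasi-clique membership
#'
#' TRUE iff the induced edge count reaches `required_edges(k, gamma)`,
#' decided in exact integer arithmetic.  With `spec$connected` the
#' induced subgraph must additionally be connected.
#'
#' @param graph a [qc_graph()].
#' @param subset node labels or 1-based indices.
#' @param spec a [qc_spec()] without `lambda`.
#' @return logical.
#' @examples
#' g <- qc_graph(cbind(c("a", "b", "c"), c("b", "c", "a")))
#' is_gamma_quasi_clique(g, c("a", "b", "c"), qc_spec("0.85"))
#' @export
is_gamma_quasi_clique <- function(graph, subset, spec) {
  stopifnot(inherits(spec, "qc_spec"))
  if (!is.null(spec$lambda))
    stop("spec has `lambda`; use is_lambda_gamma_quasi_clique()")
  idx <- resolve_subset(graph, subset)
  k <- length(idx)
  ok <- edges_within(graph, idx) >= required_edges(k, spec$gamma)
  if (ok && spec$connected) ok <- subset_connected(graph, idx)
  ok
}

#' Test (lambda,gamma)-quasi-clique membership
#'
#' TRUE iff every member vertex has at least
#' `ceiling(lambda * (k - 1))` neighbours inside the subset and the
#' gamma edge-density condition holds.  With `lambda >= 1/2` such
#' clusters have diameter at most 2, the robustness property that makes
#' gamma-cores attractive as network modules.
#'
#' @inheritParams is_gamma_quasi_clique
#' @param spec a [qc_spec()] with `lambda` set.
#' @return logical.
#' @export
is_lambda_gamma_quasi_clique <- function(graph, subset, spec) {
  stopifnot(inherits(spec, "qc_spec"))
  if (is.null(spec$lambda)) stop("spec has no `lambda`")
  idx <- resolve_subset(graph, subset)
  k <- length(idx)
  inS <- logical(graph$n); inS[idx] <- TRUE
  mindeg <- ceil_times(spec$lambda, k - 1)
  degs <- vapply(idx, function(v) sum(inS[graph$adj[[v]]]), integer(1))
  if (any(degs < mindeg)) return(FALSE)
  if (sum(degs) %/% 2L < required_edges(k, spec$gamma)) return(FALSE)
  if (spec$connected) return(subset_connected(graph, idx))
  TRUE
}

#' Diameter of an induced subgraph
#'
#' @inheritParams edge_density
#' @return the diameter (integer), or `Inf` if the induced subgraph is
#'   disconnected.
#' @export
subset_diameter <- function(graph, subset) {
  idx <- resolve_subset(graph, subset)
  if (length(idx) == 1L) return(0L)
  d <- igraph::distances(induced_igraph(graph, idx))
  m <- max(d)
  if (is.infinite(m)) Inf else as.integer(m)
}
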