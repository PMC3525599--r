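# GRASP heuristic for moderate graphs (n ~ 10^3 - 10^4).
#
# Each start builds a randomized greedy vertex permutation: candidates
# are ranked by their number of edges into the current set and the next
# vertex is drawn uniformly from the top alpha-fraction (the restricted
# candidate list).  The largest gamma-feasible prefix of the permutation
# seeds a local search of single-vertex adds and edge-increasing swaps.
# Prefix scoring is a full-lookahead variant of feasible growth: a
# temporarily infeasible prefix is retained whenever a later prefix
# becomes feasible again, which matters because quasi-cliques are not
# hereditary upward.

#' Maximum quasi-clique by GRASP
#'
#' Multi-start randomized greedy construction with local search.  The
#' returned set is always a verified gamma-quasi-clique, but carries no
#' optimality certificate (`is_optimal = FALSE`).  Deterministic for a
#' fixed seed.
#'
#' @param graph a [qc_graph()].
#' @param spec a [qc_spec()] with only `gamma` set.
#' @param iterations number of multi-start rounds (default 100).
#' @param rcl_alpha restricted-candidate-list fraction in \[0, 1\]:
#'   the next vertex is drawn from the top `ceiling(alpha * ncand)`
#'   candidates (default 0.2; 0 is pure greedy, 1 is uniform random).
#' @param seed integer RNG seed (required).
#' @return a `qc_result` with, as attribute `"trace"`, the best size
#'   after each iteration (non-decreasing).
#' @examples
#' g <- sample_gnp(100, 0.3, seed = 5)
#' max_quasi_clique_grasp(g, qc_spec("0.85"), iterations = 20, seed = 1)
#' @export
max_quasi_clique_grasp <- function(graph, spec, iterations = 100,
                                   rcl_alpha = 0.2, seed) {
  spec <- check_solver_spec(spec)
  stopifnot(iterations >= 1, rcl_alpha >= 0, rcl_alpha <= 1)
  if (missing(seed)) stop("`seed` is required for reproducibility")
  req <- required_edges_vector(graph$n, spec$gamma)
  # whole-graph shortcut: above the transition the entire vertex set is
  # feasible and no search is needed
  if (graph$m >= req[graph$n + 1]) {
    res <- verified_result(graph, seq_len(graph$n), spec, "grasp", FALSE,
                           seed = as.integer(seed))
    attr(res, "trace") <- rep(graph$n, iterations)
    return(res)
  }
  ans <- withr::with_seed(as.integer(seed),
    grasp_cpp(graph$n, graph$edges - 1L, req,
              as.integer(iterations), rcl_alpha))
  res <- verified_result(graph, ans$subset + 1L, spec, "grasp", FALSE,
                         seed = as.integer(seed))
  attr(res, "trace") <- ans$trace
  res
}
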