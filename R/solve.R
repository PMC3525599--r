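# Exact maximum quasi-clique engines.
#
# All engines return a qc_result whose vertex set has been re-verified
# through the membership predicate before return -- a defence against
# solver tolerance artifacts (the MIP backend) and plain bugs (the rest).

qc_result <- function(graph, idx, engine, optimal, seed = NULL) {
  idx <- sort(as.integer(idx))
  k <- length(idx)
  ew <- edges_within(graph, idx)
  res <- structure(list(
    vertices = graph$labels[idx],
    size = k,
    edges_within = ew,
    density = if (k > 1) ew / (k * (k - 1) / 2) else 1,
    is_optimal = isTRUE(optimal),
    engine = as.character(engine),
    seed = seed), class = "qc_result")
  res
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf(
    "<qc_result> size %d (%s%s), %d internal edges, density %.4f\n  {%s}\n",
    x$size, x$engine, if (x$is_optimal) ", optimal" else "",
    x$edges_within, x$density,
    paste(x$vertices, collapse = ", ")))
  invisible(x)
}

check_solver_spec <- function(spec) {
  stopifnot(inherits(spec, "qc_spec"))
  if (!is.null(spec$lambda) || spec$connected)
    stop("solver engines optimize the gamma-density objective only; ",
         "use the membership predicates for lambda/connectivity checks")
  spec
}

# verify a solver's answer before returning it
verified_result <- function(graph, idx, spec, engine, optimal, seed = NULL) {
  if (!is_gamma_quasi_clique(graph, idx, spec))
    stop("internal error: engine '", engine,
         "' returned an infeasible set")  # nocov
  qc_result(graph, idx, engine, optimal, seed)
}

#' Maximum quasi-clique by exhaustive enumeration (oracle)
#'
#' Enumerates vertex subsets in decreasing size and returns the first
#' feasible one, which is a maximum gamma-quasi-clique (among optima,
#' the lexicographically smallest label set).  Exponential in `n`:
#' refuses `n > 22` unless `k_cap` restricts the subset size.
#'
#' @param graph a [qc_graph()].
#' @param spec a [qc_spec()] with only `gamma` set.
#' @param k_cap optional cap on the subset sizes searched.
#' @return a `qc_result` with `is_optimal = TRUE` (optimal among sizes
#'   `<= k_cap` when a cap is given).
#' @examples
#' g <- sample_gnp(10, 0.5, seed = 7)
#' max_quasi_clique_bruteforce(g, qc_spec("0.85"))
#' @export
max_quasi_clique_bruteforce <- function(graph, spec, k_cap = NULL) {
  spec <- check_solver_spec(spec)
  if (is.null(k_cap)) {
    if (graph$n > 22)
      stop("n = ", graph$n, " is too large for exhaustive enumeration; ",
           "set `k_cap` or use max_quasi_clique_exact()")
    k_cap <- graph$n
  }
  # search in label-sorted vertex order so ties break lexicographically
  ord <- order(graph$labels)
  remap <- match(seq_len(graph$n), ord)
  ed <- cbind(remap[graph$edges[, 1]], remap[graph$edges[, 2]])
  req <- required_edges_vector(graph$n, spec$gamma)
  sub0 <- brute_force_cpp(graph$n, ed - 1L, req, as.integer(k_cap))
  verified_result(graph, ord[sub0 + 1L], spec, "brute", TRUE)
}

#' Maximum quasi-clique by branch and bound
#'
#' Provably optimal maximum gamma-quasi-clique search.  Target sizes are
#' searched upward; by quasi-heredity (every size-k quasi-clique
#' contains a size-(k-1) one) the first infeasible size proves
#' optimality of the last feasible one.  Partial sets are pruned with a
#' best-case edge-count bound over descending-degree candidate lists.
#'
#' @param graph a [qc_graph()].
#' @param spec a [qc_spec()] with only `gamma` set.
#' @param max_nodes search-node budget; when exhausted the incumbent is
#'   returned with `is_optimal = FALSE` and a warning.
#' @return a `qc_result`.
#' @examples
#' g <- sample_gnp(40, 0.2, seed = 11)
#' max_quasi_clique_exact(g, qc_spec("0.85"))
#' @export
max_quasi_clique_exact <- function(graph, spec, max_nodes = Inf) {
  spec <- check_solver_spec(spec)
  req <- required_edges_vector(graph$n, spec$gamma)
  ans <- bnb_cpp(graph$n, graph$edges - 1L, req,
                 if (is.finite(max_nodes)) max_nodes else 9e15)
  if (!ans$optimal)
    warning("node budget exhausted at incumbent size ",
            length(ans$subset), "; bound not proven")
  verified_result(graph, ans$subset + 1L, spec, "bnb", ans$optimal)
}

#' Maximum quasi-clique, engine dispatcher
#'
#' Thin front end over the brute-force, branch-and-bound, MIP and GRASP
#' engines, mirroring the command-line interface.
#'
#' @param graph a [qc_graph()].
#' @param gamma density threshold (decimal string or numeric), or a
#'   [qc_spec()].
#' @param engine one of `"bnb"`, `"brute"`, `"mip"`, `"grasp"`.
#' @param ... passed on to the engine
#'   (e.g. `iterations`, `rcl_alpha`, `seed` for GRASP; `backend` for
#'   MIP; `k_cap` for brute force).
#' @return a `qc_result`.
#' @export
max_quasi_clique <- function(graph, gamma,
                             engine = c("bnb", "brute", "mip", "grasp"),
                             ...) {
  engine <- match.arg(engine)
  spec <- if (inherits(gamma, "qc_spec")) gamma else qc_spec(gamma)
  switch(engine,
         bnb = max_quasi_clique_exact(graph, spec, ...),
         brute = max_quasi_clique_bruteforce(graph, spec, ...),
         mip = solve_mip(build_mip(graph, spec$gamma), ...),
         grasp = max_quasi_clique_grasp(graph, spec, ...))
}
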