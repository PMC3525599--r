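# Mixed-integer linear formulation of the maximum quasi-clique problem.
#
# The natural 0-1 program maximizes sum(x_i) subject to the nonconvex
# quadratic density constraint
#   sum_{(i,j) in E} x_i x_j >= gamma * sum_{i<j} x_i x_j.
# Each product x_i x_j is replaced by a continuous w_ij in [0,1] tied to
# the binaries by four linear inequalities (w <= x_i, w <= x_j,
# w >= x_i + x_j - 1, w >= 0), giving a MILP with n binaries,
# C(n,2) continuous variables and 4*C(n,2) + 1 constraints.  The density
# row is cleared of denominators with the exact rational gamma = a/b:
#   sum_E (b - a) w_ij - sum_{non-edge} a w_ij >= 0,
# so backend feasibility tolerances cannot misclassify boundary
# densities.

#' Build the maximum quasi-clique MILP
#'
#' @param graph a [qc_graph()].
#' @param gamma density threshold (decimal string, numeric, or
#'   [qc_rational()]).
#' @return an object of class `qc_mip`: the graph, the rational gamma,
#'   deterministic variable names (`x_<label>`, `w_<l1>_<l2>` over
#'   label-sorted pairs), and the variable/constraint counts
#'   (`n_binary`, `n_continuous`, `n_constraints`).
#' @examples
#' g <- qc_graph(cbind(c("a", "b", "c"), c("b", "c", "d")))
#' build_mip(g, "0.85")
#' @export
build_mip <- function(graph, gamma) {
  stopifnot(inherits(graph, "qc_graph"))
  gamma <- qc_rational(gamma)
  n <- graph$n
  ord <- order(graph$labels)          # stable, label-sorted variable order
  pairs <- if (n >= 2) t(utils::combn(ord, 2)) else
    matrix(integer(0), ncol = 2)
  lab <- function(i) gsub("[^A-Za-z0-9]", "_", graph$labels[i])
  edge_key <- if (graph$m)
    paste(pmin(graph$edges[, 1], graph$edges[, 2]),
          pmax(graph$edges[, 1], graph$edges[, 2])) else character(0)
  is_edge <- paste(pmin(pairs[, 1], pairs[, 2]),
                   pmax(pairs[, 1], pairs[, 2])) %in% edge_key
  structure(list(
    graph = graph, gamma = gamma,
    order = ord, pairs = pairs, is_edge = is_edge,
    x_names = paste0("x_", lab(ord)),
    w_names = if (nrow(pairs)) paste0("w_", lab(pairs[, 1]), "_",
                                      lab(pairs[, 2])) else character(0),
    n_binary = n, n_continuous = nrow(pairs),
    n_constraints = 4 * nrow(pairs) + 1),
    class = "qc_mip")
}

#' @export
print.qc_mip <- function(x, ...) {
  cat(sprintf(
    "<qc_mip> %d binary + %d continuous variables, %d constraints, gamma = %g/%g\n",
    x$n_binary, x$n_continuous, x$n_constraints,
    x$gamma$num, x$gamma$den))
  invisible(x)
}

#' Serialize a quasi-clique MILP in LP format
#'
#' Deterministic CPLEX-LP text serialization of a [build_mip()] model;
#' the `w >= 0` side of each linearization appears as a variable bound,
#' as is idiomatic in the LP format.
#'
#' @param model a `qc_mip`.
#' @param path file path, or `NULL` to return the lines invisibly.
#' @return invisibly, the character vector of lines.
#' @export
write_lp <- function(model, path = NULL) {
  stopifnot(inherits(model, "qc_mip"))
  a <- model$gamma$num; b <- model$gamma$den
  dens <- paste(ifelse(model$is_edge,
                       sprintf("+ %g %s", b - a, model$w_names),
                       sprintf("- %g %s", a, model$w_names)),
                collapse = " ")
  lines <- c(
    "Maximize",
    paste(" obj:", paste(model$x_names, collapse = " + ")),
    "Subject To")
  for (q in seq_len(model$n_continuous)) {
    xi <- model$x_names[match(model$pairs[q, 1], model$order)]
    xj <- model$x_names[match(model$pairs[q, 2], model$order)]
    w <- model$w_names[q]
    lines <- c(lines,
               sprintf(" l%d_a: %s - %s <= 0", q, w, xi),
               sprintf(" l%d_b: %s - %s <= 0", q, w, xj),
               sprintf(" l%d_c: %s + %s - %s <= 1", q, xi, xj, w))
  }
  lines <- c(lines, paste(" density:", dens, ">= 0"),
             "Bounds",
             sprintf(" 0 <= %s <= 1", model$w_names),
             "Binary",
             paste(" ", model$x_names),
             "End")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' MILP backend using Python scipy (HiGHS)
#'
#' Returns a backend function for [solve_mip()] that solves the model
#' with `scipy.optimize.milp` (the HiGHS solver) through the `python`
#' interpreter on the PATH.  The backend contract: a function taking a
#' `qc_mip` and returning `list(status, x)` where `status` is
#' `"optimal"` on a proven optimum and `x` is the binary vector in the
#' model's variable order.
#'
#' @param python path to the Python interpreter.
#' @return a backend function.
#' @export
milp_backend_scipy <- function(python = Sys.which("python")) {
  if (!nzchar(python))
    stop("no `python` interpreter found on the PATH")
  script <- system.file("python", "milp_backend.py", package = "qclique")
  force(script)
  function(model) {
    stopifnot(inherits(model, "qc_mip"))
    fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
    on.exit(unlink(c(fin, fout)), add = TRUE)
    g <- model$graph
    jsonlite::write_json(list(
      n = g$n,
      edges = if (g$m) g$edges - 1L else matrix(integer(0), ncol = 2),
      gamma_num = model$gamma$num,
      gamma_den = model$gamma$den), fin, auto_unbox = TRUE)
    rc <- system2(python, c(script, fin, fout), stdout = NULL)
    if (rc != 0 || !file.exists(fout))
      stop("scipy MILP backend failed (exit code ", rc, ")")
    out <- jsonlite::read_json(fout, simplifyVector = TRUE)
    list(status = if (isTRUE(out$status == 0)) "optimal" else "failed",
         x = as.numeric(out$x))
  }
}

#' Solve a quasi-clique MILP
#'
#' Hands the model to a pluggable MILP backend, rounds the binary
#' solution at 0.5, and re-verifies feasibility through the membership
#' predicate before returning.  The branch-and-bound engine
#' ([max_quasi_clique_exact()]) remains fully functional without any
#' backend.
#'
#' @param model a `qc_mip` from [build_mip()].
#' @param backend a backend function (default [milp_backend_scipy()]).
#' @return a `qc_result` with `engine = "mip"` and `is_optimal = TRUE`
#'   when the backend proves optimality.
#' @export
solve_mip <- function(model, backend = milp_backend_scipy()) {
  stopifnot(inherits(model, "qc_mip"), is.function(backend))
  sol <- backend(model)
  if (!identical(sol$status, "optimal"))
    stop("MILP backend did not prove optimality (status: ",
         sol$status, ")")
  take <- sol$x >= 0.5                  # in graph vertex order
  idx <- which(take)
  if (!length(idx)) idx <- 1L           # degenerate: empty incumbent
  spec <- qc_spec(model$gamma)
  verified_result(model$graph, idx, spec, "mip", TRUE)
}
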