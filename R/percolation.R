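# Dense-percolation experiment pipeline: sweep the edge probability p
# at fixed gamma and n, aggregate maximum quasi-clique sizes across
# replicates, and compare with the analytic bounds and the theoretical
# step function.  Replicate r uses seed `seed_base + r`, so every sweep
# is reproducible from its arguments alone.  p values may be supplied
# as decimal strings; the string form is carried into the output table
# to keep TSV keys free of float drift.

solve_one <- function(graph, spec, engine, seed, iterations, rcl_alpha,
                      max_nodes) {
  req_n <- required_edges(graph$n, spec$gamma)
  if (graph$m >= req_n)                 # whole-graph density check
    return(qc_result(graph, seq_len(graph$n), engine,
                     engine %in% c("bnb", "brute"), seed))
  switch(engine,
         bnb = max_quasi_clique_exact(graph, spec, max_nodes = max_nodes),
         brute = max_quasi_clique_bruteforce(graph, spec),
         grasp = max_quasi_clique_grasp(graph, spec,
                                        iterations = iterations,
                                        rcl_alpha = rcl_alpha,
                                        seed = seed))
}

#' Sweep edge probability and record maximum quasi-clique sizes
#'
#' For each `p` in `p_grid`, generates `reps` Erdos-Renyi graphs
#' `G(n, p)` with seeds `seed_base + 1, ..., seed_base + reps`, solves
#' each with the requested engine, and aggregates the maximum
#' quasi-clique sizes.
#'
#' @param n graph size.
#' @param p_grid edge probabilities; numeric, or decimal strings which
#'   are kept verbatim in the output `p` column.
#' @param gamma density threshold (decimal string or numeric).
#' @param reps replicates per grid point (>= 1).
#' @param engine `"bnb"` (exact; `n` limited by `exact_limit`),
#'   `"brute"`, or `"grasp"`.
#' @param seed_base integer; replicate `r` uses seed `seed_base + r`.
#' @param iterations,rcl_alpha GRASP parameters.
#' @param exact_limit refuse exact engines above this `n` (default 150).
#' @param max_nodes branch-and-bound node budget per instance.
#' @return a data.frame with one row per grid point: `n`, `p`
#'   (character), `gamma`, `reps`, `engine`, `mean_size`, `min_size`,
#'   `max_size`, `sd_size`, `mean_relative`, `seed_base`; the per-
#'   replicate sizes are attached as the `"sizes"` attribute (a list).
#' @examples
#' sweep_density(30, c("0.1", "0.3"), "0.85", reps = 3, engine = "bnb",
#'               seed_base = 1)
#' @export
sweep_density <- function(n, p_grid, gamma, reps, engine = c("bnb", "grasp",
                                                             "brute"),
                          seed_base, iterations = 100, rcl_alpha = 0.2,
                          exact_limit = 150, max_nodes = Inf) {
  engine <- match.arg(engine)
  stopifnot(reps >= 1)
  if (engine %in% c("bnb", "brute") && n > exact_limit)
    stop("exact engine requested for n = ", n, " > ", exact_limit,
         "; use engine = \"grasp\"")
  spec <- qc_spec(gamma)
  p_str <- as.character(p_grid)
  p_num <- as.numeric(p_str)
  if (anyNA(p_num) || any(p_num < 0 | p_num > 1))
    stop("`p_grid` values must lie in [0, 1]")
  rows <- vector("list", length(p_num))
  sizes_list <- vector("list", length(p_num))
  for (i in seq_along(p_num)) {
    sizes <- vapply(seq_len(reps), function(r) {
      seed <- as.integer(seed_base + r)
      g <- sample_gnp(n, p_num[i], seed = seed)
      solve_one(g, spec, engine, seed, iterations, rcl_alpha,
                max_nodes)$size
    }, numeric(1))
    sizes_list[[i]] <- sizes
    rows[[i]] <- data.frame(
      n = n, p = p_str[i], gamma = spec$gamma$value, reps = reps,
      engine = engine, mean_size = mean(sizes), min_size = min(sizes),
      max_size = max(sizes),
      sd_size = if (reps > 1) sd(sizes) else 0,
      mean_relative = mean(sizes) / n, seed_base = seed_base,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "sizes") <- sizes_list
  out
}

#' Theoretical limiting curve of the relative dense-cluster size
#'
#' The asymptotic relative size of the maximum gamma-quasi-clique in
#' `G(n,p)` is a step function of `p`: 0 below `gamma` (the largest
#' dense cluster is only logarithmic in `n`) and 1 above (the whole
#' graph is w.h.p. dense enough).  The boundary point `p = gamma` is
#' emitted as 1; whether the dense phase includes the boundary exactly
#' is a limiting-case convention, documented rather than asserted.
#'
#' @param gamma density threshold.
#' @param p_grid probabilities (numeric or decimal strings).
#' @return a data.frame with columns `p` (character) and `limit`.
#' @export
step_function_reference <- function(gamma, p_grid) {
  gamma <- qc_rational(gamma)
  p_str <- as.character(p_grid)
  p_num <- as.numeric(p_str)
  data.frame(p = p_str,
             limit = as.numeric(p_num >= gamma$value - 1e-12),
             stringsAsFactors = FALSE)
}

#' Replicate the small-graph bound-vs-experiment table
#'
#' For each `(gamma, p)` pair: the analytic lower/upper size bounds and
#' the empirical mean/min/max maximum quasi-clique size over `reps`
#' exact solves on `G(n, p)`.
#'
#' @param gammas density thresholds (decimal strings or numerics).
#' @param p_grid edge probabilities.
#' @param n graph size (default 100, exact-engine scale).
#' @param reps replicates per cell (default 100).
#' @param seed_base integer seed base.
#' @param engine exact engine (default `"bnb"`).
#' @return a data.frame with columns `gamma`, `p`, `bound_lo`,
#'   `bound_hi`, `mean`, `min`, `max`.
#' @export
replicate_table1 <- function(gammas, p_grid, n = 100, reps = 100,
                             seed_base = 1, engine = "bnb") {
  rows <- list()
  for (gam in gammas) {
    gam <- qc_rational(gam)
    sw <- sweep_density(n, p_grid, gam, reps = reps, engine = engine,
                        seed_base = seed_base)
    b <- vapply(as.numeric(as.character(p_grid)), function(p)
      quasi_clique_size_bounds(n, p, gam), numeric(2))
    rows[[length(rows) + 1L]] <- data.frame(
      gamma = gam$value, p = sw$p,
      bound_lo = b["lower", ], bound_hi = b["upper", ],
      mean = sw$mean_size, min = sw$min_size, max = sw$max_size,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative-size curves across graph sizes
#'
#' GRASP-based sweep of the mean relative maximum quasi-clique size
#' over a `p` grid for several `n`, suitable to overlay against
#' [step_function_reference()].  Near the transition the grid is
#' typically refined to steps of 0.01.
#'
#' @param n_list graph sizes.
#' @param gamma density threshold.
#' @param p_grid edge probabilities (numeric or decimal strings).
#' @param reps replicates per point.
#' @param iterations,rcl_alpha GRASP parameters.
#' @param seed_base integer seed base.
#' @return a data.frame with columns `n`, `p` (character),
#'   `mean_size`, `mean_relative`.
#' @export
sweep_relative_curve <- function(n_list, gamma, p_grid, reps = 1,
                                 iterations = 50, rcl_alpha = 0.2,
                                 seed_base = 1) {
  rows <- lapply(n_list, function(n) {
    sw <- sweep_density(n, p_grid, gamma, reps = reps, engine = "grasp",
                        seed_base = seed_base, iterations = iterations,
                        rcl_alpha = rcl_alpha)
    data.frame(n = n, p = sw$p, mean_size = sw$mean_size,
               mean_relative = sw$mean_relative,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a sweep table as TSV
#'
#' Fixed-header, tab-separated serialization; identical inputs produce
#' byte-identical files.
#'
#' @param table a data.frame from the sweep functions.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_sweep_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
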