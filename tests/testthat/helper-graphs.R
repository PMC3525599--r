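# Small graph constructors used across the suite.  Labels are letters
# (then l1, l2, ... past 26) so lexicographic tie-break tests are easy
# to reason about.

glabels <- function(k) {
  if (k <= 26) letters[seq_len(k)] else paste0("l", seq_len(k))
}

complete_graph <- function(k) {
  lb <- glabels(k)
  e <- t(utils::combn(lb, 2))
  qc_graph(e)
}

cycle_graph <- function(k) {
  lb <- glabels(k)
  qc_graph(cbind(lb, lb[c(2:k, 1)]))
}

path_graph <- function(k) {
  lb <- glabels(k)
  qc_graph(cbind(lb[-k], lb[-1]))
}

star_graph <- function(k) {          # hub 'a' plus k - 1 leaves
  lb <- glabels(k)
  qc_graph(cbind(lb[1], lb[-1]))
}

edgeless_graph <- function(k) {
  qc_graph(matrix(character(0), ncol = 2), labels = glabels(k))
}

# independent feasibility oracle used by the solver tests: R-side
# enumeration over utils::combn, no shared code with the C++ engines
feasible_sizes_oracle <- function(graph, gamma) {
  vapply(seq_len(graph$n), function(k) {
    if (k == 1) return(TRUE)
    need <- required_edges(k, gamma)
    any(utils::combn(graph$n, k, FUN = function(s)
      qclique:::edges_within(graph, s)) >= need)
  }, logical(1))
}
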