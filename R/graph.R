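# Graph container and edge-list I/O.
#
# A qc_graph is a simple undirected graph: opaque string node labels in
# first-appearance order, 1-based adjacency lists, and an edge matrix.
# Internal indices never leak into files; biological edge lists carry
# gene/protein names, which is what the label column preserves.

new_qc_graph <- function(labels, edge_idx) {
  n <- length(labels)
  if (anyDuplicated(labels)) stop("duplicate node labels")
  edge_idx <- matrix(as.integer(edge_idx), ncol = 2)
  if (nrow(edge_idx)) {
    swap <- edge_idx[, 1] > edge_idx[, 2]
    edge_idx[swap, ] <- edge_idx[swap, c(2, 1)]
    edge_idx <- edge_idx[order(edge_idx[, 1], edge_idx[, 2]), , drop = FALSE]
  }
  adj <- rep(list(integer(0)), n)
  if (nrow(edge_idx)) {
    both <- rbind(edge_idx, edge_idx[, c(2, 1), drop = FALSE])
    adj <- unname(split(both[, 2], factor(both[, 1], levels = seq_len(n))))
    adj <- lapply(adj, function(v) sort(as.integer(v)))
  }
  structure(list(labels = labels, adj = adj, edges = edge_idx,
                 n = n, m = nrow(edge_idx)),
            class = "qc_graph")
}

#' Construct a graph from an edge table
#'
#' @param edges a two-column matrix or data.frame of endpoint labels
#'   (character) for each undirected edge.  Duplicate edges are
#'   collapsed with a warning; self-loops are an error.
#' @param labels optional character vector of node labels; defaults to
#'   the labels in first-appearance order over `edges`.  Supplying
#'   `labels` is the way to carry isolated vertices.
#' @return an object of class `qc_graph` with fields `labels`, `adj`
#'   (1-based adjacency lists), `edges`, `n` and `m`.
#' @examples
#' g <- qc_graph(cbind(c("a", "b"), c("b", "c")))
#' g$n; g$m
#' @export
qc_graph <- function(edges, labels = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2) stop("`edges` needs two columns")
  a <- as.character(edges[, 1]); b <- as.character(edges[, 2])
  if (any(a == b)) stop("self-loop on node '", a[which(a == b)[1]], "'")
  if (is.null(labels)) labels <- unique(c(rbind(a, b)))
  labels <- as.character(labels)
  ia <- match(a, labels); ib <- match(b, labels)
  if (anyNA(ia) || anyNA(ib)) stop("edge endpoint not in `labels`")
  key <- paste(pmin(ia, ib), pmax(ia, ib))
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate edge(s) collapsed")
    keep <- !duplicated(key)
    ia <- ia[keep]; ib <- ib[keep]
  }
  new_qc_graph(labels, cbind(ia, ib))
}

#' @export
print.qc_graph <- function(x, ...) {
  cat(sprintf("<qc_graph> %d nodes, %d edges\n", x$n, x$m))
  invisible(x)
}

#' Read a whitespace-separated edge list
#'
#' Parses the plain-text edge-list format: one edge per line as two
#' whitespace-separated node labels, `#` starting a comment line.  A
#' comment of the form `# vertices: a b c ...` (written by
#' [write_edge_list()]) declares the full vertex set, so isolated
#' vertices survive a round trip.  Duplicate edges are collapsed with a
#' warning; a self-loop or a line with fewer than two tokens is an
#' error naming the offending line.
#'
#' @param source a file path or a character vector of lines.
#' @return a [qc_graph()].
#' @export
read_edge_list <- function(source) {
  # a single string without newlines or whitespace is taken as a path;
  # anything else is parsed as edge-list content
  looks_like_path <- length(source) == 1L && !grepl("[\n#[:space:]]", source)
  lines <- if (looks_like_path) {
    if (!file.exists(source)) stop("edge-list file not found: ", source)
    readLines(source)
  } else unlist(strsplit(source, "\n", fixed = TRUE))
  labels <- character(0)
  from <- character(0); to <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      if (grepl("^#\\s*vertices:", ln)) {
        body <- sub("^#\\s*vertices:\\s*", "", ln)
        labels <- c(labels, strsplit(body, "\\s+")[[1]])
      }
      next
    }
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) < 2)
      stop("line ", i, ": expected two node labels, got '", ln, "'")
    if (tok[1] == tok[2])
      stop("line ", i, ": self-loop on node '", tok[1], "'")
    from <- c(from, tok[1]); to <- c(to, tok[2])
  }
  labels <- unique(c(labels, c(rbind(from, to))))
  if (!length(labels)) stop("empty edge list: no vertices found")
  qc_graph(cbind(from, to), labels = labels)
}

#' Write an edge list
#'
#' Serializes a graph as one `label1<TAB>label2` line per edge, preceded
#' by a `# vertices:` header carrying all node labels (so isolated
#' vertices are preserved).  `read_edge_list(write_edge_list(g))` is the
#' identity up to vertex order.
#'
#' @param graph a [qc_graph()].
#' @param path file path, or `NULL` to return the lines invisibly.
#' @return invisibly, the character vector of lines written.
#' @export
write_edge_list <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "qc_graph"))
  lines <- c(paste("# vertices:", paste(graph$labels, collapse = " ")),
             if (graph$m) paste(graph$labels[graph$edges[, 1]],
                                graph$labels[graph$edges[, 2]], sep = "\t"))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Sample an Erdos-Renyi G(n,p) graph
#'
#' Each of the `choose(n, 2)` node pairs is linked independently with
#' probability `p`.  The seed is mandatory: the same `(n, p, seed)`
#' always yields the identical edge set, which is what makes the
#' stochastic sweep experiments reproducible.
#'
#' @param n number of vertices (>= 1).
#' @param p link probability in \[0, 1\].
#' @param seed integer RNG seed.
#' @param labels optional node labels (default `v1..vn`).
#' @return a [qc_graph()].
#' @examples
#' g <- sample_gnp(30, 0.2, seed = 1)
#' @export
sample_gnp <- function(n, p, seed, labels = NULL) {
  stopifnot(n >= 1, length(p) == 1L)
  if (is.na(p) || p < 0 || p > 1) stop("`p` must lie in [0, 1]")
  if (missing(seed)) stop("`seed` is required for reproducibility")
  if (is.null(labels)) labels <- paste0("v", seq_len(n))
  ed <- withr::with_seed(as.integer(seed), sample_gnp_cpp(n, p))
  new_qc_graph(labels, ed + 1L)
}

#' Plant a feasible dense subset in a G(n,p) background
#'
#' Samples a `G(n, p)` background graph, picks a random `k`-subset and
#' tops it up with uniformly chosen missing internal pairs until its
#' internal edge count reaches `required_edges(k, gamma)`.  The planted
#' set is therefore a gamma-quasi-clique by construction, which makes
#' this the standard solver test fixture.
#'
#' @param n,p background Erdos-Renyi parameters.
#' @param k planted subset size (`k <= n`).
#' @param gamma density threshold in (0, 1\], decimal string or numeric.
#' @param seed integer RNG seed.
#' @return a list with elements `graph` (a [qc_graph()]) and `planted`
#'   (character vector of the planted node labels).
#' @export
plant_dense_subset <- function(n, p, k, gamma, seed) {
  if (k > n) stop("`k` must not exceed `n`")
  gamma <- qc_rational(gamma)
  need <- required_edges(k, gamma)
  withr::with_seed(as.integer(seed), {
    ed <- sample_gnp_cpp(n, p) + 1L
    planted <- sort(sample.int(n, k))
    pairs <- t(utils::combn(planted, 2))
    key <- paste(pairs[, 1], pairs[, 2])
    have <- if (nrow(ed)) paste(ed[, 1], ed[, 2]) else character(0)
    present <- key %in% have
    short <- need - sum(present)
    if (short > 0) {
      add <- sample(which(!present), short)
      ed <- rbind(ed, pairs[add, , drop = FALSE])
    }
    g <- new_qc_graph(paste0("v", seq_len(n)), ed)
    list(graph = g, planted = g$labels[planted])
  })
}

# ---- internal helpers ----

# resolve a user-supplied subset (labels or 1-based indices) to indices
resolve_subset <- function(graph, subset) {
  if (!length(subset)) stop("empty subset")
  if (is.character(subset)) {
    idx <- match(subset, graph$labels)
    if (anyNA(idx)) stop("unknown node label(s): ",
                         paste(subset[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(subset)
    if (anyNA(idx) || any(idx < 1L | idx > graph$n))
      stop("subset indices out of range")
  }
  if (anyDuplicated(idx)) stop("duplicated vertices in subset")
  idx
}

# internal edge count of an induced subgraph
edges_within <- function(graph, idx) {
  inS <- logical(graph$n)
  inS[idx] <- TRUE
  sum(vapply(idx, function(v) sum(inS[graph$adj[[v]]]), integer(1))) %/% 2L
}

# convert (a subset of) a qc_graph to igraph for path-based measures
induced_igraph <- function(graph, idx) {
  inS <- logical(graph$n)
  inS[idx] <- TRUE
  keep <- graph$edges[inS[graph$edges[, 1]] & inS[graph$edges[, 2]], ,
                      drop = FALSE]
  remap <- match(seq_len(graph$n), idx)
  igraph::make_graph(t(cbind(remap[keep[, 1]], remap[keep[, 2]])),
                     n = length(idx), directed = FALSE)
}
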