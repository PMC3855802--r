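#' Directed acyclic graph over named variables
#'
#' Internally the graph is a logical adjacency matrix `adj[parent, child]`.
#' Construction rejects self-loops, unknown endpoints and directed cycles.
#'
#' @param nodes Character vector of variable names.
#' @param edges Optional two-column matrix or data frame of (parent, child)
#'   pairs.
#' @return An object of class `bn_dag`.
#' @export
bn_dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop_usage("duplicate node names")
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  if (!is.null(edges) && NROW(edges) > 0L) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop_usage("edges must have two columns")
    for (i in seq_len(nrow(edges))) {
      u <- edges[i, 1L]; v <- edges[i, 2L]
      if (!(u %in% nodes) || !(v %in% nodes))
        stop_usage("edge endpoint not among nodes: ", u, " -> ", v)
      if (u == v) stop_usage("self-loop on '", u, "'")
      adj[u, v] <- TRUE
    }
  }
  if (!adj_is_acyclic(adj)) stop_usage("graph contains a directed cycle")
  structure(list(nodes = nodes, adj = adj), class = "bn_dag")
}

dag_from_adj <- function(adj) {
  structure(list(nodes = rownames(adj), adj = adj), class = "bn_dag")
}

# Kahn's algorithm; also used as the acyclicity test.
adj_topo_order <- function(adj) {
  n <- nrow(adj)
  indeg <- colSums(adj)
  order <- integer(0)
  avail <- which(indeg == 0)
  indeg[avail] <- NA
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]
    order <- c(order, v)
    ch <- which(adj[v, ])
    for (c in ch) {
      indeg[c] <- indeg[c] - 1L
      if (!is.na(indeg[c]) && indeg[c] == 0L) {
        avail <- c(avail, c)
        indeg[c] <- NA
      }
    }
  }
  if (length(order) < n) NULL else order
}

adj_is_acyclic <- function(adj) !is.null(adj_topo_order(adj))

# TRUE if a directed path from -> to exists.
adj_has_path <- function(adj, from, to) {
  seen <- logical(nrow(adj))
  stack <- from
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, which(adj[v, ] & !seen))
  }
  FALSE
}

#' Topological ordering of a DAG
#' @param dag A [bn_dag()].
#' @return Character vector of node names, parents before children.
#' @export
topological_order <- function(dag) dag$nodes[adj_topo_order(dag$adj)]

#' Parents of a node
#' @param dag A [bn_dag()].
#' @param node Node name.
#' @return Character vector of parent names (in node order).
#' @export
dag_parents <- function(dag, node) dag$nodes[dag$adj[, node]]

#' Children of a node
#' @param dag A [bn_dag()].
#' @param node Node name.
#' @return Character vector of child names.
#' @export
dag_children <- function(dag, node) dag$nodes[dag$adj[node, ]]

#' Edge list of a DAG
#' @param dag A [bn_dag()].
#' @return Data frame with columns `from`, `to`.
#' @export
dag_edges <- function(dag) {
  idx <- which(dag$adj, arr.ind = TRUE)
  data.frame(from = dag$nodes[idx[, 1L]], to = dag$nodes[idx[, 2L]],
             stringsAsFactors = FALSE)
}

#' Number of edges
#' @param dag A [bn_dag()].
#' @return Integer edge count.
#' @export
dag_n_edges <- function(dag) sum(dag$adj)

#' @export
print.bn_dag <- function(x, ...) {
  cat(sprintf("<bn_dag> %d nodes, %d edges\n", length(x$nodes), sum(x$adj)))
  e <- dag_edges(x)
  if (nrow(e)) {
    ord <- order(e$from, e$to)
    cat(paste0("  ", e$from[ord], " -> ", e$to[ord], collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Test two DAGs for equality of node and edge sets
#' @param a,b [bn_dag()] objects.
#' @return Logical.
#' @export
dag_equal <- function(a, b) {
  setequal(a$nodes, b$nodes) &&
    identical(a$adj[a$nodes, a$nodes], b$adj[a$nodes, a$nodes])
}

#' Write a DAG as a 0/1 adjacency matrix CSV
#'
#' Rows are parents, columns children; the first CSV column holds the node
#' names.
#'
#' @param dag A [bn_dag()].
#' @param path Output file path.
#' @export
write_dag_csv <- function(dag, path) {
  m <- matrix(as.integer(dag$adj), nrow(dag$adj),
              dimnames = dimnames(dag$adj))
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Read a DAG from an adjacency matrix CSV
#' @param path File written by [write_dag_csv()].
#' @return A [bn_dag()].
#' @export
read_dag_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m) || !all(rownames(m) == colnames(m)))
    stop_usage("adjacency CSV must be square with matching row/column names")
  adj <- m == 1
  if (!adj_is_acyclic(adj)) stop_usage("adjacency matrix encodes a cycle")
  dag_from_adj(adj)
}

#' Export a DAG in Graphviz DOT format
#' @param dag A [bn_dag()].
#' @param path Output file path.
#' @export
write_dag_dot <- function(dag, path) {
  e <- dag_edges(dag)
  lines <- c("digraph bn {",
             paste0("  \"", dag$nodes, "\";"),
             if (nrow(e)) paste0("  \"", e$from, "\" -> \"", e$to, "\";"),
             "}")
  writeLines(lines, path)
  invisible(path)
}
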