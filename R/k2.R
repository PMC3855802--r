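#' K2 greedy structure search under a node ordering
#'
#' Visits each node in the given order and greedily adds, from among the
#' node's predecessors, the single parent whose addition most improves the
#' node's family score, stopping when no addition improves it or the parent
#' cap is reached. No edge ever points against the ordering. Additions are
#' strictly improving, so per-node family scores are monotone over the
#' greedy steps. Ties are broken towards the earlier candidate in the
#' ordering.
#'
#' @param data A [bn_dataset()].
#' @param order Character vector: a permutation of all variables.
#' @param max_parents Cap on parents per node (default 4).
#' @return A [bn_dag()].
#' @export
k2_search <- function(data, order, max_parents = 4L) {
  nodes <- var_names(data)
  if (!setequal(order, nodes) || length(order) != length(nodes))
    stop_usage("order must be a permutation of the dataset variables")
  scorer <- make_family_scorer(data)
  edges <- NULL
  for (i in seq_along(order)) {
    v <- order[i]
    preds <- order[seq_len(i - 1L)]
    parents <- character(0)
    current <- scorer(v, parents)
    repeat {
      if (length(parents) >= max_parents) break
      cand <- setdiff(preds, parents)
      if (!length(cand)) break
      gains <- vapply(cand, function(u) scorer(v, c(parents, u)), 0)
      best <- which.max(gains)
      if (gains[best] <= current) break
      parents <- c(parents, cand[best])
      current <- gains[best]
    }
    if (length(parents))
      edges <- rbind(edges, cbind(parents, v))
  }
  bn_dag(nodes, edges)
}
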