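# Aggregation of per-fold structures into one final DAG via a maximum-weight
# directed spanning structure (maximum branching) over edge frequencies.

# Chu-Liu/Edmonds maximum branching on a weight matrix w[u, v] (> 0 means a
# candidate edge). Each node keeps at most one incoming edge; cycles among
# the locally best choices are contracted and resolved recursively. Ties are
# broken towards the lexicographically smaller parent so the result is
# deterministic.
max_branching <- function(w) {
  n <- nrow(w)
  nodes <- rownames(w)
  eps <- 1e-12
  best_in <- integer(n)  # 0 = no parent
  for (v in seq_len(n)) {
    cand <- which(w[, v] > eps)
    cand <- cand[cand != v]
    if (!length(cand)) next
    mx <- max(w[cand, v])
    best_in[v] <- min(cand[w[cand, v] >= mx - eps])
  }
  # find a cycle among the chosen edges
  cycle <- NULL
  state <- integer(n)
  for (start in seq_len(n)) {
    if (state[start]) next
    path <- integer(0)
    v <- start
    while (v != 0L && state[v] == 0L) {
      state[v] <- 2L  # on current path
      path <- c(path, v)
      v <- best_in[v]
    }
    if (v != 0L && state[v] == 2L) {
      cycle <- path[seq(match(v, path), length(path))]
      break
    }
    state[path] <- 1L
  }
  if (is.null(cycle)) {
    sel <- which(best_in > 0L)
    return(cbind(best_in[sel], sel))
  }
  # contract the cycle into a supernode and recurse on adjusted weights
  in_cycle <- seq_len(n) %in% cycle
  cyc_w <- vapply(cycle, function(v) w[best_in[v], v], 0)
  w_min <- min(cyc_w)
  keep <- which(!in_cycle)
  m <- length(keep) + 1L
  super <- m
  labels <- c(nodes[keep], ".super.")
  w2 <- matrix(0, m, m, dimnames = list(labels, labels))
  w2[seq_along(keep), seq_along(keep)] <- w[keep, keep]
  entry <- integer(m)  # which cycle node an edge into the supernode targets
  for (ui in seq_along(keep)) {
    u <- keep[ui]
    # into the cycle: standard adjustment against the replaced cycle edge
    adj_w <- w[u, cycle] - cyc_w + w_min
    ok <- w[u, cycle] > eps
    if (any(ok)) {
      bi <- which(ok)[which.max(adj_w[which(ok)])]
      w2[ui, super] <- adj_w[bi]
      entry[ui] <- cycle[bi]
    }
    # out of the cycle: best cycle-internal source
    from <- w[cycle, u]
    if (any(from > eps)) w2[super, ui] <- max(from)
  }
  sub <- max_branching(w2)
  edges <- NULL
  super_parent <- 0L
  super_entry <- 0L
  out_sources <- integer(length(keep))
  if (!is.null(sub) && nrow(sub)) {
    for (k in seq_len(nrow(sub))) {
      u2 <- sub[k, 1L]; v2 <- sub[k, 2L]
      if (v2 == super) {
        super_parent <- keep[u2]
        super_entry <- entry[u2]
      } else if (u2 == super) {
        v <- keep[v2]
        from <- w[cycle, v]
        src <- cycle[which.max(from)]
        edges <- rbind(edges, c(src, v))
      } else {
        edges <- rbind(edges, c(keep[u2], keep[v2]))
      }
    }
  }
  # expand the cycle: keep all its edges except the one displaced by the
  # external entry edge, or the minimum-weight edge if nothing enters
  drop_v <- if (super_entry > 0L) super_entry else cycle[which.min(cyc_w)]
  for (v in cycle) {
    if (v == drop_v) next
    edges <- rbind(edges, c(best_in[v], v))
  }
  if (super_parent > 0L)
    edges <- rbind(edges, c(super_parent, super_entry))
  edges
}

#' Aggregate cross-validation DAGs into a final structure
#'
#' Each directed edge is weighted by the fraction of input DAGs containing
#' it, and a maximum-weight directed spanning structure (a maximum
#' branching: every node keeps at most one parent, no cycles) is extracted
#' from the frequency graph. Disconnected components yield a forest, which
#' is returned as-is. Unanimous trees are recovered exactly.
#'
#' @param dags Non-empty list of [bn_dag()]s over the same variable set.
#' @return A [bn_dag()] with attribute `edge_frequency` (the weight matrix).
#' @export
aggregate_dags <- function(dags) {
  if (!length(dags)) stop_usage("need at least one DAG to aggregate")
  nodes <- dags[[1L]]$nodes
  for (d in dags) {
    if (!setequal(d$nodes, nodes))
      stop_usage("all DAGs must share the same variable set")
  }
  freq <- Reduce(`+`, lapply(dags, function(d)
    (d$adj[nodes, nodes]) * 1)) / length(dags)
  edges <- max_branching(freq)
  dag <- if (is.null(edges) || !nrow(edges)) bn_dag(nodes) else
    bn_dag(nodes, cbind(nodes[edges[, 1L]], nodes[edges[, 2L]]))
  attr(dag, "edge_frequency") <- freq
  dag
}
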