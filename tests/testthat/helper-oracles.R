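# Independent oracles: brute-force enumeration, direct factorial evaluation
# of the structure score, and pairwise AUC counting. These deliberately
# avoid the code paths they check.

# Full-joint table: one row per complete assignment with its probability.
enum_joint <- function(net) {
  nodes <- net$dag$nodes
  g <- expand.grid(lapply(nodes, function(v)
    seq_along(net$variables[[v]]$states)), KEEP.OUT.ATTRS = FALSE)
  names(g) <- nodes
  g$prob <- vapply(seq_len(nrow(g)), function(i)
    joint_probability(net, as.list(g[i, nodes])), 0)
  g
}

oracle_posterior <- function(net, query, evidence = NULL) {
  g <- enum_joint(net)
  keep <- rep(TRUE, nrow(g))
  for (v in names(evidence)) {
    s <- evidence[[v]]
    idx <- if (is.numeric(s)) s else match(s, net$variables[[v]]$states)
    keep <- keep & g[[v]] == idx
  }
  p <- tapply(g$prob[keep], g[[query]][keep], sum)
  out <- numeric(length(net$variables[[query]]$states))
  out[as.integer(names(p))] <- p
  out / sum(out)
}

# CPT entry lookup by explicit per-parent strides (first parent fastest).
cpt_entry <- function(cpt, assignment) {
  row <- 1L
  stride <- 1L
  for (k in seq_along(cpt$parents)) {
    row <- row + (assignment[[cpt$parents[k]]] - 1L) * stride
    stride <- stride * length(cpt$parent_states[[k]])
  }
  cpt$prob[row, assignment[[cpt$child]]]
}

# Truncated-factorisation oracle for P(outcome | evidence, do(target = t)):
# sum over all assignments consistent with the evidence and the clamped
# target of the product of every CPT except the target's.
oracle_interventional <- function(net, target, value, outcome,
                                  evidence = NULL) {
  nodes <- net$dag$nodes
  g <- expand.grid(lapply(nodes, function(v)
    seq_along(net$variables[[v]]$states)), KEEP.OUT.ATTRS = FALSE)
  names(g) <- nodes
  vidx <- if (is.numeric(value)) value else
    match(value, net$variables[[target]]$states)
  keep <- g[[target]] == vidx
  for (v in names(evidence)) {
    s <- evidence[[v]]
    idx <- if (is.numeric(s)) s else match(s, net$variables[[v]]$states)
    keep <- keep & g[[v]] == idx
  }
  g <- g[keep, , drop = FALSE]
  w <- vapply(seq_len(nrow(g)), function(i) {
    prod(vapply(setdiff(nodes, target), function(v)
      cpt_entry(net$cpts[[v]], as.list(g[i, nodes])), 0))
  }, 0)
  p <- tapply(w, g[[outcome]], sum)
  out <- numeric(length(net$variables[[outcome]]$states))
  out[as.integer(names(p))] <- p
  out / sum(out)
}

# Direct factorial-formula evaluation of the K2 score from the raw record
# matrix, with log factorials accumulated as explicit integer-log sums.
log_factorial <- function(m) sum(log(seq_len(m)))

oracle_k2_score <- function(x, dag, cards) {
  total <- 0
  for (v in dag$nodes) {
    r <- cards[[v]]
    pa <- dag_parents(dag, v)
    if (length(pa)) {
      cfgs <- unique(x[, pa, drop = FALSE])
      for (ci in seq_len(nrow(cfgs))) {
        rows <- rep(TRUE, nrow(x))
        for (p in pa) rows <- rows & x[, p] == cfgs[ci, p]
        counts <- tabulate(x[rows, v], nbins = r)
        total <- total + log_factorial(r - 1L) -
          log_factorial(sum(counts) + r - 1L) +
          sum(vapply(counts, log_factorial, 0))
      }
    } else {
      counts <- tabulate(x[, v], nbins = r)
      total <- total + log_factorial(r - 1L) -
        log_factorial(sum(counts) + r - 1L) +
        sum(vapply(counts, log_factorial, 0))
    }
  }
  total
}

# AUC by counting every positive-negative pair, ties worth one half.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Maximum-weight branching by exhaustive enumeration of parent functions
# (each node: no parent or one of the others), keeping only acyclic
# selections. Practical up to ~5 nodes.
brute_branching_weight <- function(w) {
  n <- nrow(w)
  choices <- lapply(seq_len(n), function(v) c(0L, setdiff(seq_len(n), v)))
  best <- 0
  rec <- function(v, parent) {
    if (v > n) {
      adj <- matrix(FALSE, n, n)
      wt <- 0
      for (u in seq_len(n)) {
        if (parent[u] > 0L) {
          if (w[parent[u], u] <= 1e-12) return(invisible())
          adj[parent[u], u] <- TRUE
          wt <- wt + w[parent[u], u]
        }
      }
      if (lungbn:::adj_is_acyclic(adj) && wt > best) best <<- wt
      return(invisible())
    }
    for (ch in choices[[v]]) {
      parent[v] <- ch
      rec(v + 1L, parent)
    }
  }
  rec(1L, integer(n))
  best
}
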