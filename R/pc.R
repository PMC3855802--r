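# Constraint-based discovery: PC/IC-style skeleton from conditional-
# independence tests, v-structure orientation, Meek propagation, and a
# deterministic tier/lexicographic orientation of whatever remains.

# G-squared conditional independence test of x_i vs x_j given a set of
# conditioning columns. Returns list(p_value, skipped): the test is skipped
# (with a warning) when the sample cannot support its degrees of freedom.
g2_test <- function(x, i, j, cond, cards, min_per_cell = 5) {
  n <- nrow(x)
  ri <- cards[i]; rj <- cards[j]
  rs <- if (length(cond)) prod(cards[cond]) else 1L
  df <- (ri - 1L) * (rj - 1L) * rs
  if (df <= 0 || n < min_per_cell * ri * rj * rs) {
    return(list(p_value = NA_real_, skipped = TRUE))
  }
  strata <- parent_config_index(x, cond, cards)
  g2 <- 0
  for (s in unique(strata)) {
    rows <- strata == s
    tab <- matrix(tabulate((x[rows, j] - 1L) * ri + x[rows, i],
                           nbins = ri * rj), nrow = ri)
    ns <- sum(tab)
    if (ns == 0) next
    expected <- outer(rowSums(tab), colSums(tab)) / ns
    pos <- tab > 0
    g2 <- g2 + 2 * sum(tab[pos] * log(tab[pos] / expected[pos]))
  }
  list(p_value = stats::pchisq(g2, df, lower.tail = FALSE), skipped = FALSE)
}

all_subsets <- function(v, size) {
  if (size == 0L) return(list(integer(0)))
  if (length(v) < size) return(list())
  # length(v) == size short-circuits combn's scalar-means-seq_len pitfall
  if (length(v) == size) return(list(v))
  utils::combn(v, size, simplify = FALSE)
}

#' Constraint-based structure discovery
#'
#' PC/IC-style learning: the skeleton is pruned by G-squared conditional
#' independence tests with conditioning sets of growing size, unshielded
#' colliders are oriented as v-structures, Meek's rules propagate
#' orientations, and any remaining undirected edges are oriented by temporal
#' tier, then lexicographically, which keeps the output a DAG and makes it
#' deterministic. Tests whose degrees of freedom the sample cannot support
#' are skipped with a warning and the edge is kept.
#'
#' @param data A [bn_dataset()].
#' @param alpha Significance level for the independence tests.
#' @param max_cond Largest conditioning-set size tried (default 3).
#' @param tiers Optional named tier vector used for the residual
#'   orientation; defaults to the dataset's declared tiers.
#' @return A [bn_dag()].
#' @export
constraint_learn <- function(data, alpha = 0.01, max_cond = 3L, tiers = NULL) {
  if (alpha <= 0 || alpha >= 1) stop_usage("alpha must lie in (0, 1)")
  nodes <- var_names(data)
  p <- length(nodes)
  cds <- cards(data)
  x <- data$x
  tiers <- tiers %||% tiers_from_variables(data)
  und <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  und[upper.tri(und)] <- TRUE
  und <- und | t(und)
  sepsets <- list()
  skipped_any <- FALSE
  for (l in 0:max_cond) {
    for (a in seq_len(p - 1L)) {
      for (b in seq((a + 1L), p)) {
        if (!und[a, b]) next
        adj_a <- setdiff(which(und[a, ]), b)
        for (S in all_subsets(adj_a, l)) {
          res <- g2_test(x, a, b, S, cds)
          if (res$skipped) { skipped_any <- TRUE; next }
          if (res$p_value > alpha) {
            und[a, b] <- und[b, a] <- FALSE
            sepsets[[paste(a, b)]] <- S
            break
          }
        }
      }
    }
  }
  if (skipped_any)
    warning("some independence tests were skipped (insufficient sample for their df); edges kept")
  # v-structures: a - c - b with a,b non-adjacent and c outside sepset(a, b)
  dir <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  for (c in seq_len(p)) {
    nb <- which(und[c, ])
    if (length(nb) < 2L) next
    for (pair in all_subsets(nb, 2L)) {
      a <- pair[1L]; b <- pair[2L]
      if (und[a, b] || dir[a, b] || dir[b, a]) next
      S <- sepsets[[paste(min(a, b), max(a, b))]]
      if (!is.null(S) && !(c %in% S)) {
        dir[a, c] <- TRUE; dir[b, c] <- TRUE
        und[a, c] <- und[c, a] <- und[b, c] <- und[c, b] <- FALSE
      }
    }
  }
  # Meek rules 1-3
  repeat {
    changed <- FALSE
    for (a in seq_len(p)) for (b in seq_len(p)) {
      if (!und[a, b]) next
      # R1: c -> a and c, b non-adjacent  =>  a -> b
      if (any(dir[, a] & !und[, b] & !dir[, b] & !dir[b, ] &
              seq_len(p) != b)) {
        dir[a, b] <- TRUE; und[a, b] <- und[b, a] <- FALSE
        changed <- TRUE; next
      }
      # R2: directed path a -> c -> b  =>  a -> b
      if (any(dir[a, ] & dir[, b])) {
        dir[a, b] <- TRUE; und[a, b] <- und[b, a] <- FALSE
        changed <- TRUE; next
      }
      # R3: a - c1 -> b, a - c2 -> b, c1, c2 non-adjacent  =>  a -> b
      cs <- which(und[a, ] & dir[, b])
      if (length(cs) >= 2L) {
        pairs <- all_subsets(cs, 2L)
        if (any(vapply(pairs, function(q)
              !und[q[1L], q[2L]] && !dir[q[1L], q[2L]] && !dir[q[2L], q[1L]],
              TRUE))) {
          dir[a, b] <- TRUE; und[a, b] <- und[b, a] <- FALSE
          changed <- TRUE; next
        }
      }
    }
    if (!changed) break
  }
  # residual orientation: earlier tier first, then lexicographic
  key <- order(tiers[nodes], nodes)
  pos <- match(seq_len(p), key)
  for (a in seq_len(p - 1L)) for (b in seq((a + 1L), p)) {
    if (!und[a, b]) next
    if (pos[a] < pos[b]) dir[a, b] <- TRUE else dir[b, a] <- TRUE
    und[a, b] <- und[b, a] <- FALSE
  }
  # drop any edge that closes a directed cycle (can arise from conflicting
  # orientations on non-faithful data); deterministic order
  adj <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  idx <- which(dir, arr.ind = TRUE)
  if (nrow(idx)) {
    ord <- order(idx[, 1L], idx[, 2L])
    for (k in ord) {
      a <- idx[k, 1L]; b <- idx[k, 2L]
      if (!adj_has_path(adj, b, a)) adj[a, b] <- TRUE
      else warning("dropping edge ", nodes[a], " -> ", nodes[b],
                   " to keep the graph acyclic")
    }
  }
  dag_from_adj(adj)
}
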