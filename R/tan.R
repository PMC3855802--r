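# Tree-augmented naive Bayes structure.

# Conditional mutual information I(Xi; Xj | C) from empirical frequencies.
conditional_mutual_information <- function(x, i, j, c_col, cards) {
  n <- nrow(x)
  ri <- cards[i]; rj <- cards[j]; rc <- cards[c_col]
  key <- (x[, c_col] - 1L) * ri * rj + (x[, j] - 1L) * ri + x[, i]
  nijc <- array(tabulate(key, nbins = ri * rj * rc), dim = c(ri, rj, rc))
  cmi <- 0
  for (cc in seq_len(rc)) {
    slab <- nijc[, , cc]
    nc <- sum(slab)
    if (nc == 0) next
    pij <- slab / nc
    pi_ <- rowSums(pij); pj_ <- colSums(pij)
    pos <- pij > 0
    expected <- outer(pi_, pj_)
    cmi <- cmi + (nc / n) * sum(pij[pos] * log(pij[pos] / expected[pos]))
  }
  cmi
}

#' Learn a tree-augmented naive Bayes structure
#'
#' The class variable points at every predictor; predictors additionally
#' form a tree (at most one predictor parent each) chosen to maximise the
#' total conditional mutual information `I(Xi; Xj | class)`, i.e. a maximum
#' spanning tree over the pairwise CMI weights, oriented away from the root.
#'
#' @param data A [bn_dataset()].
#' @param class_var Name of the class (outcome) variable.
#' @param root Predictor used as the tree root; defaults to the first
#'   predictor in column order.
#' @return A [bn_dag()] with attribute `cmi` (the weight matrix).
#' @export
learn_tan <- function(data, class_var, root = NULL) {
  nodes <- var_names(data)
  if (!class_var %in% nodes) stop_usage("unknown class variable: ", class_var)
  preds <- setdiff(nodes, class_var)
  if (length(preds) < 2L) stop_usage("TAN needs at least two predictors")
  cds <- cards(data)
  c_col <- match(class_var, nodes)
  if (length(unique(data$x[, c_col])) < 2L)
    stop_usage("class variable is constant; TAN is degenerate")
  p <- length(preds)
  w <- matrix(0, p, p, dimnames = list(preds, preds))
  for (a in seq_len(p - 1L)) {
    for (b in seq((a + 1L), p)) {
      w[a, b] <- w[b, a] <- conditional_mutual_information(
        data$x, match(preds[a], nodes), match(preds[b], nodes), c_col, cds)
    }
  }
  # Prim's algorithm; deterministic tie-break towards earlier predictors.
  root <- root %||% preds[1L]
  if (!root %in% preds) stop_usage("root must be a predictor")
  in_tree <- root
  tree_edges <- NULL
  while (length(in_tree) < p) {
    best <- NULL
    for (u in in_tree) {
      for (v in setdiff(preds, in_tree)) {
        if (is.null(best) || w[u, v] > best$w) best <- list(u = u, v = v, w = w[u, v])
      }
    }
    tree_edges <- rbind(tree_edges, cbind(best$u, best$v))
    in_tree <- c(in_tree, best$v)
  }
  edges <- rbind(cbind(class_var, preds), tree_edges)
  dag <- bn_dag(nodes, edges)
  attr(dag, "cmi") <- w
  dag
}
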