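# Vectorised posterior prediction when every non-query variable is observed.
#
# With complete evidence the posterior of the query reduces to its Markov
# blanket: P(q = s | rest) is proportional to the product of the query's own
# CPT entry and the CPT entries of its children evaluated with q = s. This
# is the prediction path used by cross-validation and the concordance
# analysis, where the explicit-missingness encoding makes every record
# complete.

#' Posterior of one variable given all other columns, row by row
#'
#' @param net A `bn_fit` network whose variables all appear in `data` with
#'   identical state spaces.
#' @param data A [bn_dataset()].
#' @param query Name of the queried variable; its recorded column is ignored.
#' @return Numeric matrix, rows = records, columns = query states; each row
#'   sums to 1.
#' @export
predict_posterior <- function(net, data, query) {
  nm <- var_names(data)
  if (!query %in% net$dag$nodes) stop_usage("unknown query variable: ", query)
  if (length(setdiff(net$dag$nodes, nm)))
    stop_usage("data does not cover the network's variables")
  cds <- cards(data)
  for (v in net$dag$nodes) {
    if (length(net$variables[[v]]$states) != cds[[v]])
      stop_usage("state space mismatch for '", v, "'")
  }
  x <- data$x
  n <- nrow(x)
  r <- cds[[query]]
  qcol <- match(query, nm)
  logp <- matrix(0, n, r)
  fams <- c(query, dag_children(net$dag, query))
  for (v in fams) {
    cpt <- net$cpts[[v]]
    pa_cols <- match(cpt$parents, nm)
    vcol <- match(v, nm)
    for (s in seq_len(r)) {
      xs <- x
      xs[, qcol] <- s
      j <- parent_config_index(xs, pa_cols, cds)
      child_val <- if (v == query) rep.int(s, n) else x[, vcol]
      logp[, s] <- logp[, s] + log(cpt$prob[cbind(j, child_val)])
    }
  }
  p <- exp(logp - row_log_sum_exp(logp))
  colnames(p) <- net$variables[[query]]$states
  p
}
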