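# Exact inference by factor elimination.
#
# A factor is a list(vars, dims, vals) with vals stored in linear order, the
# first variable varying fastest. The 13 registry variables have small
# arities, so exact elimination is cheap; correctness (rather than the
# message-passing mechanism) is the contract, and it is pinned against
# full-joint enumeration oracles in the tests.

new_factor <- function(vars, dims, vals) {
  list(vars = vars, dims = as.integer(dims), vals = as.numeric(vals))
}

factor_from_cpt <- function(cpt) {
  # prob is configs x child-states with first parent fastest, so the column-
  # major vector is already in (parents..., child) linear order.
  dims <- c(vapply(cpt$parent_states, length, 0L), length(cpt$states))
  new_factor(c(cpt$parents, cpt$child), dims, as.vector(cpt$prob))
}

# For each cell of the grid over (out_vars, out_dims), the linear index into
# a factor holding variables f_vars (a subset of out_vars).
factor_cell_index <- function(out_vars, out_dims, f_vars, f_dims) {
  n <- prod(out_dims)
  idx <- rep.int(1, n)
  stride <- 1
  for (k in seq_along(f_vars)) {
    pos <- match(f_vars[k], out_vars)
    inner <- if (pos > 1L) prod(out_dims[seq_len(pos - 1L)]) else 1
    coord <- rep(rep(seq_len(out_dims[pos]), each = inner),
                 length.out = n)
    idx <- idx + (coord - 1) * stride
    stride <- stride * f_dims[k]
  }
  idx
}

factor_product <- function(a, b) {
  vars <- union(a$vars, b$vars)
  dims <- integer(length(vars))
  dims[match(a$vars, vars)] <- a$dims
  dims[match(b$vars, vars)] <- b$dims
  ia <- factor_cell_index(vars, dims, a$vars, a$dims)
  ib <- factor_cell_index(vars, dims, b$vars, b$dims)
  new_factor(vars, dims, a$vals[ia] * b$vals[ib])
}

factor_marginalise <- function(f, var) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  if (length(f$vars) == 1L)
    return(new_factor(character(0), integer(0), sum(f$vals)))
  a <- array(f$vals, dim = f$dims)
  keep <- setdiff(seq_along(f$dims), pos)
  vals <- apply(a, keep, sum)
  new_factor(f$vars[keep], f$dims[keep], vals)
}

factor_reduce <- function(f, var, state) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  a <- array(f$vals, dim = f$dims)
  args <- rep(list(quote(expr = )), length(f$dims))
  args[[pos]] <- state
  sliced <- do.call(`[`, c(list(a), args, list(drop = FALSE)))
  keep <- setdiff(seq_along(f$dims), pos)
  new_factor(f$vars[keep], f$dims[keep], as.vector(sliced))
}

# Sum-product variable elimination with a greedy smallest-intermediate-factor
# ordering. Returns a factor over `keep`.
eliminate_to <- function(factors, keep) {
  elim <- setdiff(unique(unlist(lapply(factors, `[[`, "vars"))), keep)
  while (length(elim)) {
    # cost of eliminating v = size of the product of factors mentioning v
    costs <- vapply(elim, function(v) {
      touching <- factors[vapply(factors, function(f) v %in% f$vars, TRUE)]
      vars <- unique(unlist(lapply(touching, `[[`, "vars")))
      dims <- vapply(vars, function(u) {
        for (f in touching) {
          p <- match(u, f$vars)
          if (!is.na(p)) return(f$dims[p])
        }
        1L
      }, 0L)
      prod(dims)
    }, 0)
    v <- elim[which.min(costs)]
    elim <- setdiff(elim, v)
    hit <- vapply(factors, function(f) v %in% f$vars, TRUE)
    prod_f <- Reduce(factor_product, factors[hit])
    factors <- c(factors[!hit], list(factor_marginalise(prod_f, v)))
  }
  Reduce(factor_product, factors)
}

check_evidence <- function(net, evidence) {
  if (is.null(evidence) || length(evidence) == 0L) return(integer(0))
  if (anyDuplicated(names(evidence)))
    stop_usage("a variable appears more than once in the evidence")
  assignment_indices(net, evidence, vars = names(evidence))
}

#' Exact posterior distribution of a query variable
#'
#' Computes `P(query | evidence)` by sum-product variable elimination on the
#' network's CPT factors. Evidence with zero probability under the network is
#' an error (it signals a data/state mismatch) rather than a NaN vector.
#'
#' @param net A `bn_fit` network.
#' @param query Name of the queried variable.
#' @param evidence Named vector/list of observed states (labels or indices);
#'   may be empty.
#' @return Named probability vector over the query's states (sums to 1).
#' @export
posterior <- function(net, query, evidence = NULL) {
  if (!query %in% net$dag$nodes) stop_usage("unknown query variable: ", query)
  ev <- check_evidence(net, evidence)
  if (query %in% names(ev)) stop_usage("query variable cannot be in evidence")
  factors <- lapply(net$cpts, factor_from_cpt)
  for (v in names(ev)) {
    factors <- lapply(factors, factor_reduce, var = v, state = ev[[v]])
  }
  res <- eliminate_to(factors, query)
  vals <- res$vals
  if (length(res$vars) == 1L && res$vars != query)
    stop_usage("internal: elimination did not isolate the query")
  z <- sum(vals)
  if (!is.finite(z) || z <= 0)
    stop_usage("evidence has zero probability under the network")
  out <- vals / z
  names(out) <- net$variables[[query]]$states
  out
}

#' Cut the incoming edges of an intervened variable
#'
#' Implements the graph surgery of a do-operator intervention: every edge
#' into `target` is removed and the target's CPT is replaced by a parent-free
#' marginal table, leaving all other CPTs untouched. By default the marginal
#' is obtained exactly from the network itself; supplying `data` instead
#' re-learns it as a smoothed empirical marginal (used when the recommender
#' is re-parameterised on training data).
#'
#' @param net A `bn_fit` network.
#' @param target Name of the intervened variable.
#' @param data Optional [bn_dataset()] from which to estimate the target's
#'   marginal (with `pseudocount` smoothing).
#' @param pseudocount Dirichlet pseudocount for the data-based marginal.
#' @return A `bn_fit` with the mutilated graph. Idempotent.
#' @export
mutilate <- function(net, target, data = NULL, pseudocount = 1) {
  if (!target %in% net$dag$nodes) stop_usage("unknown variable: ", target)
  pa <- dag_parents(net$dag, target)
  states <- net$variables[[target]]$states
  r <- length(states)
  if (is.null(data)) {
    if (!length(pa)) return(net)
    marg <- as.numeric(posterior(net, target))
  } else {
    counts <- tabulate(data$x[, match(target, var_names(data))], nbins = r)
    marg <- (counts + pseudocount) / (sum(counts) + r * pseudocount)
  }
  adj <- net$dag$adj
  adj[, target] <- FALSE
  dag <- dag_from_adj(adj)
  cpts <- net$cpts
  cpts[[target]] <- new_cpt(target, character(0), states, list(),
                            matrix(marg, nrow = 1L),
                            net$cpts[[target]]$pseudocount)
  structure(list(dag = dag, cpts = cpts, variables = net$variables),
            class = "bn_fit")
}

#' Interventional survival probability under a forced treatment
#'
#' Answers `P(outcome = state | evidence, do(target = value))`: the incoming
#' edges of `target` are removed (if the supplied network is already
#' mutilated this is a no-op), the forced value is entered as evidence on the
#' parent-free target, and the posterior of the outcome is read off. For a
#' parentless target this coincides with ordinary conditioning.
#'
#' @param net A `bn_fit`, mutilated at `target` or not.
#' @param target Intervened variable (e.g. the treatment plan).
#' @param value Forced state of `target`.
#' @param outcome Queried variable (e.g. 1-year survival); must differ from
#'   `target`.
#' @param evidence Named observed states, not including `target`.
#' @param state Outcome state whose probability is returned (default
#'   `"Alive"`).
#' @return A probability.
#' @export
interventional_survival <- function(net, target, value, outcome,
                                    evidence = NULL, state = "Alive") {
  if (identical(target, outcome)) stop_usage("outcome must differ from target")
  if (target %in% names(evidence))
    stop_usage("the intervened variable cannot also be evidence")
  net_do <- mutilate(net, target)
  ev <- c(stats::setNames(list(value), target), as.list(evidence %||% list()))
  post <- posterior(net_do, outcome, ev)
  if (!state %in% names(post))
    stop_usage("'", state, "' is not a state of '", outcome, "'")
  unname(post[[state]])
}
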