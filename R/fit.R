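# Conditional probability tables and parameter estimation.

# Parent-configuration row index for each record, with the *first* parent
# varying fastest (expand.grid convention). `x` is the integer record matrix.
parent_config_index <- function(x, parent_cols, cards) {
  n <- nrow(x)
  if (length(parent_cols) == 0L) return(rep.int(1L, n))
  idx <- rep.int(1L, n)
  stride <- 1L
  for (p in parent_cols) {
    idx <- idx + (x[, p] - 1L) * stride
    stride <- stride * cards[p]
  }
  idx
}

new_cpt <- function(child, parents, states, parent_states, prob, pseudocount) {
  structure(list(child = child, parents = parents, states = states,
                 parent_states = parent_states, prob = prob,
                 pseudocount = pseudocount),
            class = "bn_cpt")
}

#' @export
print.bn_cpt <- function(x, ...) {
  cat(sprintf("<cpt> %s | %s  (%d rows x %d states)\n", x$child,
              if (length(x$parents)) paste(x$parents, collapse = ", ") else "-",
              nrow(x$prob), ncol(x$prob)))
  invisible(x)
}

# Labelled parent configurations in row order (first parent fastest).
cpt_config_grid <- function(cpt) {
  if (!length(cpt$parents)) return(NULL)
  g <- expand.grid(cpt$parent_states, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  names(g) <- cpt$parents
  g
}

#' Fit conditional probability tables for a fixed structure
#'
#' Maximum a posteriori estimates under a uniform Dirichlet prior: each CPT
#' cell is `(N_ijk + a) / (N_ij + r_i * a)` where `a` is the pseudocount,
#' `N_ijk` the number of records with child state `k` under parent
#' configuration `j`, and `r_i` the child's number of states. Parent
#' configurations never seen in the data get the uniform prior row.
#'
#' The sentinel `"Unknown/Missing"` state, where present, is counted as an
#' ordinary category: this is explicit-missingness modelling, not imputation.
#'
#' @param dag A [bn_dag()] whose nodes all appear in `data`.
#' @param data A [bn_dataset()] (fully encoded; no nulls).
#' @param pseudocount Positive Dirichlet pseudocount per cell (default 1).
#' @return A fitted network of class `bn_fit`: the DAG plus one CPT per
#'   variable.
#' @export
fit_parameters <- function(dag, data, pseudocount = 1) {
  if (!inherits(dag, "bn_dag")) stop_usage("dag must be a bn_dag")
  if (!inherits(data, "bn_dataset")) stop_usage("data must be a bn_dataset")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop_usage("pseudocount must be positive")
  nm <- var_names(data)
  missing_vars <- setdiff(dag$nodes, nm)
  if (length(missing_vars))
    stop_usage("dag variables absent from data: ",
               paste(missing_vars, collapse = ", "))
  cards <- cards(data)
  x <- data$x
  cpts <- lapply(dag$nodes, function(v) {
    r <- cards[[v]]
    pa <- dag_parents(dag, v)
    pa_cols <- match(pa, nm)
    n_cfg <- prod(cards[pa_cols])
    if (n_cfg * r > 5e7)
      stop_usage("CPT for '", v, "' would need ", n_cfg, " rows; reduce parents")
    j <- parent_config_index(x, pa_cols, cards)
    key <- (j - 1L) * r + x[, match(v, nm)]
    counts <- tabulate(key, nbins = n_cfg * r)
    N <- matrix(counts, nrow = n_cfg, ncol = r, byrow = TRUE)
    prob <- (N + pseudocount) / (rowSums(N) + r * pseudocount)
    new_cpt(v, pa, data$variables[[v]]$states,
            lapply(pa, function(p) data$variables[[p]]$states),
            prob, pseudocount)
  })
  names(cpts) <- dag$nodes
  structure(list(dag = dag, cpts = cpts,
                 variables = data$variables[dag$nodes]),
            class = "bn_fit")
}

#' @export
print.bn_fit <- function(x, ...) {
  cat(sprintf("<bn_fit> %d variables, %d edges\n",
              length(x$cpts), sum(x$dag$adj)))
  invisible(x)
}

net_cards <- function(net) {
  vapply(net$variables, function(v) length(v$states), 0L)
}

# Map a named assignment (state labels or indices) to integer indices over
# `vars`; errors on unknown variables or states.
assignment_indices <- function(net, assignment, vars = net$dag$nodes) {
  if (is.null(names(assignment)) || any(!nzchar(names(assignment))))
    stop_usage("assignment must be a named vector/list")
  unknown <- setdiff(names(assignment), net$dag$nodes)
  if (length(unknown))
    stop_usage("unknown variable(s): ", paste(unknown, collapse = ", "))
  out <- integer(length(vars)); names(out) <- vars
  for (v in vars) {
    val <- assignment[[v]]
    if (is.null(val)) stop_usage("assignment missing variable '", v, "'")
    states <- net$variables[[v]]$states
    i <- if (is.numeric(val)) as.integer(val) else match(as.character(val), states)
    if (is.na(i) || i < 1L || i > length(states))
      stop_usage("invalid state for '", v, "': ", val)
    out[[v]] <- i
  }
  out
}

#' Joint probability of a complete assignment
#'
#' Multiplies the relevant CPT entry of every variable; the factorisation of
#' the network's joint distribution.
#'
#' @param net A `bn_fit` network.
#' @param assignment Named vector/list covering every variable, with state
#'   labels or 1-based state indices.
#' @return A probability.
#' @export
joint_probability <- function(net, assignment) {
  if (length(assignment) < length(net$dag$nodes)) {
    missing_vars <- setdiff(net$dag$nodes, names(assignment))
    if (length(missing_vars))
      stop_usage("assignment must cover every variable; missing: ",
                 paste(missing_vars, collapse = ", "))
  }
  idx <- assignment_indices(net, assignment)
  p <- 1
  for (v in net$dag$nodes) {
    cpt <- net$cpts[[v]]
    pa_idx <- idx[cpt$parents]
    row <- 1L
    stride <- 1L
    for (k in seq_along(cpt$parents)) {
      row <- row + (pa_idx[k] - 1L) * stride
      stride <- stride * length(cpt$parent_states[[k]])
    }
    p <- p * cpt$prob[row, idx[[v]]]
  }
  unname(p)
}
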