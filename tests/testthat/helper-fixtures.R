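# Small builders used across the suite.

make_vars <- function(names, nstates) {
  v <- Map(function(n, r) variable_spec(n, paste0(tolower(n), seq_len(r))),
           names, nstates)
  names(v) <- names
  v
}

make_net <- function(vars, edges, cpts) {
  dag <- bn_dag(names(vars), edges)
  cpt_objs <- lapply(names(vars), function(v) {
    pa <- dag_parents(dag, v)
    prob <- cpts[[v]]
    if (is.null(dim(prob))) prob <- matrix(prob, nrow = 1L)
    lungbn:::new_cpt(v, pa, vars[[v]]$states,
                     lapply(pa, function(p) vars[[p]]$states), prob, 1)
  })
  names(cpt_objs) <- names(vars)
  structure(list(dag = dag, cpts = cpt_objs, variables = vars),
            class = "bn_fit")
}

# Random DAG + Dirichlet CPTs over p variables with 2..max_states states.
random_net <- function(p, seed, max_states = 3L, edge_prob = 0.4,
                       concentration = 1) {
  set.seed(seed)
  nms <- LETTERS[seq_len(p)]
  vars <- make_vars(nms, sample(2:max_states, p, replace = TRUE))
  ord <- sample(nms)
  edges <- NULL
  for (i in seq_len(p - 1L)) {
    for (j in seq((i + 1L), p)) {
      if (stats::runif(1) < edge_prob)
        edges <- rbind(edges, c(ord[i], ord[j]))
    }
  }
  cpts <- lapply(nms, function(v) NULL)
  names(cpts) <- nms
  dag <- bn_dag(nms, edges)
  for (v in nms) {
    r <- length(vars[[v]]$states)
    pa <- dag_parents(dag, v)
    n_cfg <- prod(vapply(pa, function(p) length(vars[[p]]$states), 0L))
    if (!length(pa)) n_cfg <- 1L
    w <- matrix(stats::rgamma(n_cfg * r, concentration) + 1e-6, n_cfg, r)
    cpts[[v]] <- w / rowSums(w)
  }
  make_net(vars, edges, cpts)
}

# A 5-variable ground-truth net with strong, hand-set dependencies,
# used for structure-recovery checks.
five_var_net <- function() {
  vars <- make_vars(c("A", "B", "C", "D", "E"), c(2L, 2L, 2L, 2L, 2L))
  edges <- rbind(c("A", "B"), c("B", "C"), c("A", "D"), c("C", "E"),
                 c("D", "E"))
  make_net(vars, edges, list(
    A = c(0.55, 0.45),
    B = rbind(c(0.85, 0.15), c(0.2, 0.8)),
    C = rbind(c(0.9, 0.1), c(0.25, 0.75)),
    D = rbind(c(0.15, 0.85), c(0.8, 0.2)),
    E = rbind(c(0.9, 0.1), c(0.3, 0.7), c(0.6, 0.4), c(0.1, 0.9))))
}
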