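# JSON serialisation of fitted networks (DAG + CPT arrays).

#' Write a fitted network to JSON
#'
#' Stores the variable declarations, the edge list and every CPT's
#' probability rows, so a network can be exchanged or reloaded without the
#' training data.
#'
#' @param net A `bn_fit`.
#' @param path Output file path.
#' @export
write_net_json <- function(net, path) {
  obj <- list(
    variables = lapply(unname(net$variables), function(v)
      list(name = v$name, states = v$states, tier = v$tier,
           has_missing_state = v$has_missing_state)),
    edges = dag_edges(net$dag),
    cpts = lapply(unname(net$cpts), function(cpt)
      list(child = cpt$child, parents = cpt$parents,
           prob = unname(apply(cpt$prob, 1L, c, simplify = FALSE)),
           pseudocount = cpt$pseudocount)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted network from JSON
#'
#' @param path File written by [write_net_json()].
#' @return A `bn_fit`.
#' @export
read_net_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE,
                             simplifyMatrix = FALSE)
  variables <- lapply(seq_len(nrow(obj$variables)), function(i) {
    row <- obj$variables[i, ]
    v <- variable_spec(row$name,
                       setdiff(unlist(row$states), .SENTINEL), row$tier)
    if (isTRUE(row$has_missing_state)) add_missing_state(v) else v
  })
  names(variables) <- vapply(variables, `[[`, "", "name")
  edges <- if (NROW(obj$edges)) as.matrix(obj$edges) else NULL
  dag <- bn_dag(names(variables), edges)
  cpts <- lapply(seq_along(obj$cpts$child), function(i) {
    child <- obj$cpts$child[i]
    parents <- unlist(obj$cpts$parents[[i]]) %||% character(0)
    prob <- do.call(rbind, obj$cpts$prob[[i]])
    new_cpt(child, parents, variables[[child]]$states,
            lapply(parents, function(p) variables[[p]]$states),
            prob, obj$cpts$pseudocount[i])
  })
  names(cpts) <- obj$cpts$child
  structure(list(dag = dag, cpts = cpts[dag$nodes],
                 variables = variables[dag$nodes]),
            class = "bn_fit")
}
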