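# Expert structural knowledge: temporal tiers and pairwise relations with
# confidence weights.

#' Expert structure prior
#'
#' Encodes the two kinds of knowledge a clinician can supply about the
#' domain graph: temporal tiers (a variable in a later tier cannot point at
#' an earlier tier) and pairwise relations, each with a confidence weight:
#'
#' * `precedes` (`A` before `B`): forbids/penalises the edge `B -> A`;
#' * `undirected_related` (`A - B`): rewards an edge between `A` and `B` in
#'   either direction;
#' * `directly_influences` (`A -> B`): rewards exactly that directed edge.
#'
#' A confidence of exactly 1 makes the constraint hard: violating structures
#' are excluded from the search outright. A confidence `c < 1` contributes
#' `log(c / (1 - c))` to the log structure prior whenever the constraint is
#' satisfied, so the search trades prior log-odds against data score.
#'
#' @param tiers Named integer vector mapping each variable to its tier index
#'   (smaller = earlier). May be `NULL` when only pairwise relations are
#'   used.
#' @param pairwise Data frame with columns `a`, `b`, `relation`
#'   (`"precedes"`, `"undirected_related"`, `"directly_influences"`) and
#'   `confidence` in (0, 1].
#' @param tier_confidence Confidence attached to the tier constraints
#'   (default 1 = hard).
#' @return An object of class `bn_structure_prior`.
#' @export
structure_prior <- function(tiers = NULL, pairwise = NULL,
                            tier_confidence = 1) {
  if (!is.null(tiers)) {
    if (is.null(names(tiers)) || anyNA(tiers))
      stop_usage("tiers must be a complete named integer vector")
    tiers <- stats::setNames(as.integer(tiers), names(tiers))
  }
  if (!is.null(pairwise) && nrow(pairwise)) {
    stopifnot(all(c("a", "b", "relation", "confidence") %in% names(pairwise)))
    if (!all(pairwise$relation %in%
             c("precedes", "undirected_related", "directly_influences")))
      stop_usage("unknown pairwise relation type")
    if (any(pairwise$confidence <= 0 | pairwise$confidence > 1))
      stop_usage("confidence must lie in (0, 1]")
    if (any(pairwise$a == pairwise$b))
      stop_usage("pairwise relations need two distinct variables")
  }
  if (tier_confidence <= 0 || tier_confidence > 1)
    stop_usage("tier_confidence must lie in (0, 1]")
  structure(list(tiers = tiers, pairwise = pairwise,
                 tier_confidence = tier_confidence),
            class = "bn_structure_prior")
}

#' Tiers from a dataset's variable declarations
#'
#' Maps the three temporal tiers (pre-treatment, treatment, post-treatment)
#' to indices 1, 2, 3.
#'
#' @param data A [bn_dataset()].
#' @return Named integer vector suitable for [structure_prior()].
#' @export
tiers_from_variables <- function(data) {
  lev <- c(pre_treatment = 1L, treatment = 2L, post_treatment = 3L)
  stats::setNames(lev[tiers_of(data)], var_names(data))
}

#' Count temporal-tier violations of a DAG
#'
#' @param dag A [bn_dag()].
#' @param tiers Named integer tier vector.
#' @return Number of edges pointing from a later tier to an earlier tier.
#' @export
tier_violations <- function(dag, tiers) {
  e <- dag_edges(dag)
  if (!nrow(e)) return(0L)
  sum(tiers[e$from] > tiers[e$to])
}

# Internal compiled view of the prior over a fixed node set:
#  - forbidden[u, v]: edge u->v can never be present (hard constraints);
#  - forced: edges that must be present (hard presence constraints);
#  - soft: data frame of soft constraints with their log-odds bonuses.
compile_prior <- function(prior, nodes) {
  p <- length(nodes)
  forbidden <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  forced <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  soft <- list()
  if (!is.null(prior$tiers)) {
    known <- intersect(nodes, names(prior$tiers))
    tiers <- prior$tiers[known]
    if (prior$tier_confidence == 1) {
      for (u in known) for (v in known)
        if (tiers[[u]] > tiers[[v]]) forbidden[u, v] <- TRUE
    } else {
      lo <- log(prior$tier_confidence / (1 - prior$tier_confidence))
      for (u in known) for (v in known)
        if (tiers[[u]] > tiers[[v]])
          soft[[length(soft) + 1L]] <-
            list(a = u, b = v, relation = "tier_forbid", bonus = lo)
    }
  }
  if (!is.null(prior$pairwise) && nrow(prior$pairwise)) {
    for (i in seq_len(nrow(prior$pairwise))) {
      row <- prior$pairwise[i, ]
      if (!(row$a %in% nodes) || !(row$b %in% nodes))
        stop_usage("prior references unknown variable(s): ", row$a, ", ", row$b)
      if (row$confidence == 1) {
        switch(row$relation,
          precedes = { forbidden[row$b, row$a] <- TRUE },
          directly_influences = {
            forced[row$a, row$b] <- TRUE
            forbidden[row$b, row$a] <- TRUE
          },
          undirected_related = {
            # some edge must connect the pair; seed a tier-consistent one
            forced[row$a, row$b] <- TRUE
          })
      } else {
        lo <- log(row$confidence / (1 - row$confidence))
        soft[[length(soft) + 1L]] <-
          list(a = row$a, b = row$b, relation = row$relation, bonus = lo)
      }
    }
  }
  if (any(forced & forbidden))
    stop_usage("contradictory hard constraints (an edge is both forced and forbidden)")
  if (any(forced & t(forced)))
    stop_usage("contradictory hard constraints (both directions forced)")
  list(forbidden = forbidden, forced = forced, soft = soft)
}

# Log structure prior contribution of the soft constraints for a given
# adjacency matrix.
soft_log_prior <- function(compiled, adj) {
  total <- 0
  for (s in compiled$soft) {
    sat <- switch(s$relation,
      tier_forbid = !adj[s$a, s$b],
      precedes = !adj[s$b, s$a],
      undirected_related = adj[s$a, s$b] || adj[s$b, s$a],
      directly_influences = adj[s$a, s$b])
    if (sat) total <- total + s$bonus
  }
  total
}
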