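# Structure learning: TAN, K2, annealing, MCMC, constraint-based discovery,
# prior-constrained search and DAG aggregation.

test_that("TAN builds class-to-all edges plus a predictor tree", {
  vars <- make_vars(c("X1", "X2", "Y"), c(2L, 2L, 2L))
  set.seed(3)
  x <- cbind(X1 = sample(1:2, 40, TRUE), X2 = sample(1:2, 40, TRUE),
             Y = sample(1:2, 40, TRUE))
  d <- bn_dataset(vars, x)
  dag <- learn_tan(d, "Y")
  e <- dag_edges(dag)
  expect_setequal(paste(e$from, e$to),
                  c("Y X1", "Y X2", "X1 X2"))
  expect_error(learn_tan(bn_dataset(vars, cbind(x[, 1:2], Y = 1L)), "Y"),
               "constant")
})

test_that("an XOR-dependent pair is always joined in the TAN tree", {
  vars <- make_vars(c("X1", "X2", "X3", "Y"), c(2L, 2L, 2L, 2L))
  set.seed(4)
  n <- 20000
  y <- sample(1:2, n, TRUE)
  x1 <- sample(1:2, n, TRUE)
  x2 <- ifelse(stats::runif(n) < 0.9, ifelse(x1 == y, 1L, 2L),
               sample(1:2, n, TRUE))            # strongly tied to X1 given Y
  x3 <- sample(1:2, n, TRUE)                    # independent of everything
  d <- bn_dataset(vars, cbind(X1 = x1, X2 = x2, X3 = x3, Y = y))
  dag <- learn_tan(d, "Y")
  e <- dag_edges(dag)
  expect_true(any((e$from == "X1" & e$to == "X2") |
                  (e$from == "X2" & e$to == "X1")))
  # CMI oracle: direct counting ranks the dependent pair highest
  w <- attr(dag, "cmi")
  expect_gt(w["X1", "X2"], w["X1", "X3"])
  expect_gt(w["X1", "X2"], w["X2", "X3"])
  # near-independent pairs carry near-zero weight but the graph is a tree
  expect_lt(w["X1", "X3"], 0.01)
  expect_equal(nrow(e), 3 + 2)  # class edges + spanning tree
})

test_that("K2 returns the empty graph on independent data", {
  vars <- make_vars(c("A", "B", "C"), c(2L, 2L, 2L))
  set.seed(5)
  x <- cbind(A = sample(1:2, 2000, TRUE), B = sample(1:2, 2000, TRUE),
             C = sample(1:2, 2000, TRUE))
  dag <- k2_search(bn_dataset(vars, x), c("A", "B", "C"))
  expect_equal(dag_n_edges(dag), 0L)
})

test_that("K2 recovers a dependent edge in the direction of the order", {
  vars <- make_vars(c("A", "B"), c(2L, 2L))
  net <- make_net(vars, rbind(c("A", "B")), list(
    A = c(0.4, 0.6), B = rbind(c(0.85, 0.15), c(0.25, 0.75))))
  d <- sample_cohort(net, 10000, seed = 6)
  scorer <- lungbn:::make_family_scorer(d)
  # oracle: adding the parent must beat not adding it, whatever the order
  expect_gt(scorer("B", "A"), scorer("B", character(0)))
  expect_gt(scorer("A", "B"), scorer("A", character(0)))
  e1 <- dag_edges(k2_search(d, c("A", "B")))
  e2 <- dag_edges(k2_search(d, c("B", "A")))
  expect_equal(paste(e1$from, e1$to), "A B")
  expect_equal(paste(e2$from, e2$to), "B A")
  expect_error(k2_search(d, "A"), "permutation")
})

test_that("annealing finds the dependence, never scores below empty, and is seeded", {
  vars <- make_vars(c("A", "B"), c(2L, 2L))
  net <- make_net(vars, rbind(c("A", "B")), list(
    A = c(0.4, 0.6), B = rbind(c(0.9, 0.1), c(0.2, 0.8))))
  d <- sample_cohort(net, 3000, seed = 7)
  cfg <- search_config(seed = 8, sweeps = 40)
  dag <- anneal_search(d, cfg)
  expect_equal(dag_n_edges(dag), 1L)  # either direction scores equally
  empty_score <- log_bayesian_score(bn_dag(c("A", "B")), d)
  expect_gte(log_bayesian_score(dag, d), empty_score)
  expect_true(dag_equal(dag, anneal_search(d, cfg)))
})

test_that("MCMC lands in the true equivalence class of a v-structure", {
  vars <- make_vars(c("A", "B", "C"), c(2L, 2L, 2L))
  net <- make_net(vars, rbind(c("A", "C"), c("B", "C")), list(
    A = c(0.6, 0.4), B = c(0.3, 0.7),
    C = rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.3, 0.7), c(0.8, 0.2))))
  d <- sample_cohort(net, 5000, seed = 9)
  cfg <- search_config(seed = 10, steps = 4000, burn_in = 1000)
  dag <- mcmc_search(d, cfg)
  # oracle: exhaustively score all 25 3-node DAGs; the v-structure is the
  # unique maximum of its class, so the chain's best must match its score
  all_edge_sets <- list(
    list(), list(c("A","B")), list(c("B","A")), list(c("A","C")),
    list(c("C","A")), list(c("B","C")), list(c("C","B")),
    list(c("A","B"), c("A","C")), list(c("A","B"), c("C","A")),
    list(c("B","A"), c("B","C")), list(c("B","A"), c("C","B")),
    list(c("A","C"), c("B","C")), list(c("C","A"), c("C","B")),
    list(c("A","C"), c("C","B")), list(c("C","A"), c("B","C")),
    list(c("A","B"), c("B","C")), list(c("B","A"), c("A","C")),
    list(c("A","B"), c("C","B")), list(c("B","A"), c("C","A")),
    list(c("A","B"), c("A","C"), c("B","C")),
    list(c("A","B"), c("A","C"), c("C","B")),
    list(c("B","A"), c("B","C"), c("A","C")),
    list(c("B","A"), c("B","C"), c("C","A")),
    list(c("C","A"), c("C","B"), c("A","B")),
    list(c("C","A"), c("C","B"), c("B","A")))
  scores <- vapply(all_edge_sets, function(es) {
    m <- if (length(es)) do.call(rbind, es) else NULL
    log_bayesian_score(bn_dag(c("A", "B", "C"), m), d)
  }, 0)
  expect_equal(log_bayesian_score(dag, d), max(scores), tolerance = 1e-9)
  # the collider itself is the top structure on this data
  expect_true(dag$adj["A", "C"] && dag$adj["B", "C"] && !dag$adj["A", "B"] &&
              !dag$adj["B", "A"])
  ef <- attr(dag, "edge_frequency")
  expect_true(all(ef >= 0 & ef <= 1))
  expect_true(dag_equal(dag, mcmc_search(d, cfg)))
})

test_that("constraint-based learning prunes, keeps and orients correctly", {
  vars <- make_vars(c("A", "B", "C"), c(2L, 2L, 2L))
  flat <- stats::setNames(rep(1L, 3), c("A", "B", "C"))
  # independent pair: no edge
  set.seed(11)
  x <- cbind(A = sample(1:2, 10000, TRUE), B = sample(1:2, 10000, TRUE))
  d2 <- bn_dataset(vars[c("A", "B")], x)
  expect_equal(dag_n_edges(constraint_learn(d2, alpha = 0.01,
                                            tiers = flat[1:2])), 0L)
  # chain: skeleton A - B - C without the shortcut
  chain <- make_net(vars, rbind(c("A", "B"), c("B", "C")), list(
    A = c(0.5, 0.5), B = rbind(c(0.9, 0.1), c(0.2, 0.8)),
    C = rbind(c(0.85, 0.15), c(0.3, 0.7))))
  dc <- sample_cohort(chain, 10000, seed = 12)
  got <- constraint_learn(dc, alpha = 0.01, tiers = flat)
  und <- got$adj | t(got$adj)
  expect_true(und["A", "B"] && und["B", "C"] && !und["A", "C"])
  # collider: oriented into C
  coll <- make_net(vars, rbind(c("A", "C"), c("B", "C")), list(
    A = c(0.6, 0.4), B = c(0.3, 0.7),
    C = rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.3, 0.7), c(0.8, 0.2))))
  dv <- sample_cohort(coll, 10000, seed = 13)
  gv <- constraint_learn(dv, alpha = 0.01, tiers = flat)
  expect_true(gv$adj["A", "C"] && gv$adj["B", "C"])
  expect_false(gv$adj["C", "A"] || gv$adj["C", "B"])
})

test_that("hard tier constraints are never violated by constrained search", {
  cfg <- generator_config()
  net <- build_truth_net(cfg)
  d <- apply_nmar(sample_cohort(net, 400, seed = 14), cfg, seed = 15)
  tiers <- tiers_from_variables(d)
  prior <- structure_prior(tiers = tiers)
  for (s in 1:5) {
    dag <- constrained_search(d, prior, search_config(seed = s, sweeps = 10))
    expect_equal(tier_violations(dag, tiers), 0L)
    expect_true(lungbn:::adj_is_acyclic(dag$adj))
  }
})

test_that("soft pairwise priors trade log-odds against the data score", {
  vars <- make_vars(c("A", "B"), c(2L, 2L))
  set.seed(16)
  x <- cbind(A = sample(1:2, 500, TRUE), B = sample(1:2, 500, TRUE))
  d <- bn_dataset(vars, x)
  scorer <- lungbn:::make_family_scorer(d)
  penalty <- scorer("B", "A") - scorer("B", character(0))  # < 0: indep data
  run <- function(conf) {
    prior <- structure_prior(pairwise = data.frame(
      a = "A", b = "B", relation = "directly_influences",
      confidence = conf, stringsAsFactors = FALSE))
    dag <- constrained_search(d, prior, search_config(seed = 17, sweeps = 30))
    dag$adj["A", "B"]
  }
  # exhaustive 2-variable table: edge included iff bonus beats the penalty
  for (conf in c(0.6, 0.9, 0.999)) {
    bonus <- log(conf / (1 - conf))
    expect_identical(run(conf), bonus + penalty > 0)
  }
  # confidence -> 1 limit: the edge is always present
  expect_true(run(0.999999))
})

test_that("aggregation recovers unanimous trees and majority directions", {
  nodes <- c("A", "B", "C", "D")
  tree <- bn_dag(nodes, rbind(c("A", "B"), c("B", "C"), c("A", "D")))
  agg <- aggregate_dags(replicate(10, tree, simplify = FALSE))
  expect_true(dag_equal(agg, tree))
  flipped <- bn_dag(nodes, rbind(c("B", "A"), c("B", "C"), c("A", "D")))
  agg2 <- aggregate_dags(c(replicate(9, tree, simplify = FALSE),
                           list(flipped)))
  expect_true(dag_equal(agg2, tree))
  # two node-disjoint unanimous trees come back as a forest
  forest <- bn_dag(nodes, rbind(c("A", "B"), c("C", "D")))
  expect_true(dag_equal(aggregate_dags(replicate(5, forest, simplify = FALSE)),
                        forest))
  expect_error(aggregate_dags(list()), "at least one")
})

test_that("the branching matches exhaustive enumeration on random weights", {
  for (s in 1:40) {
    set.seed(700 + s)
    n <- sample(3:5, 1)
    w <- matrix(round(stats::runif(n * n), 3), n, n)
    w[sample(length(w), n)] <- 0
    diag(w) <- 0
    dimnames(w) <- list(letters[1:n], letters[1:n])
    edges <- lungbn:::max_branching(w)
    got <- if (is.null(edges)) 0 else
      sum(w[cbind(edges[, 1], edges[, 2])])
    # result must be a valid branching
    if (!is.null(edges) && nrow(edges)) {
      expect_false(any(duplicated(edges[, 2])))
      adj <- matrix(FALSE, n, n)
      adj[edges] <- TRUE
      expect_true(lungbn:::adj_is_acyclic(adj))
    }
    expect_equal(got, brute_branching_weight(w), tolerance = 1e-9)
  }
})

test_that("every search output is acyclic", {
  cfg <- generator_config()
  net <- build_truth_net(cfg)
  d <- sample_cohort(net, 300, seed = 18)
  out <- list(
    k2_search(d, var_names(d)),
    anneal_search(d, search_config(seed = 1, sweeps = 5)),
    mcmc_search(d, search_config(seed = 1, steps = 500, burn_in = 100)),
    learn_tan(d, "Survival"))
  for (dag in out) expect_true(lungbn:::adj_is_acyclic(dag$adj))
})
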