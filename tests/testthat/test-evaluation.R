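# Folds, metrics, baseline classifiers and the cross-validation harness.

test_that("stratified folds balance size and prevalence deterministically", {
  vars <- make_vars(c("X", "Y"), c(2L, 2L))
  y <- c(rep(1L, 33), rep(2L, 67))
  d <- bn_dataset(vars, cbind(X = rep(1L, 100), Y = y))
  folds <- stratified_folds(d, 10, "Y", seed = 1)
  expect_length(folds, 10)
  sizes <- lengths(folds)
  expect_true(all(sizes == 10))
  pos <- vapply(folds, function(f) sum(y[f] == 1L), 0L)
  expect_true(all(pos %in% c(3L, 4L)))
  expect_identical(folds, stratified_folds(d, 10, "Y", seed = 1))
  expect_false(identical(folds, stratified_folds(d, 10, "Y", seed = 2)))
  # leave-one-out
  loo <- stratified_folds(d, 100, "Y", seed = 1)
  expect_true(all(lengths(loo) == 1L))
  expect_error(stratified_folds(d, 101, "Y"), "k must lie")
})

test_that("AUC handles the canonical cases and the worked example", {
  expect_equal(auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "single class")
})

test_that("AUC equals brute-force pairwise counting on random fixtures", {
  set.seed(2)
  for (i in 1:200) {
    n <- sample(4:25, 1)
    scores <- round(stats::runif(n), sample(1:3, 1))  # induce ties
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    expect_equal(auc(scores, labels), brute_auc(scores, labels))
  }
})

test_that("naive Bayes equals Bayes' rule and the star-network posterior", {
  vars <- make_vars(c("X", "Y"), c(2L, 2L))
  x <- cbind(X = c(1L, 1L, 2L, 2L, 2L, 1L), Y = c(1L, 1L, 1L, 2L, 2L, 2L))
  d <- bn_dataset(vars, x)
  s <- naive_bayes_fit_predict(d, d, "Y", positive = "y1")
  # smoothed tables: P(Y=1) = 4/8; P(X|Y) with pseudocount 1
  p_y1 <- 4 / 8
  p_x_y1 <- c(3, 2) / 5   # counts (2,1) + 1 over 3 + 2
  p_x_y2 <- c(2, 3) / 5
  want1 <- p_y1 * p_x_y1[1] / (p_y1 * p_x_y1[1] + (1 - p_y1) * p_x_y2[1])
  expect_equal(s[1], want1)
  # cross-implementation: identical to posterior() on the star DAG
  star <- bn_dag(c("X", "Y"), rbind(c("Y", "X")))
  net <- fit_parameters(star, d, 1)
  for (i in 1:6) {
    want <- posterior(net, "Y", list(X = x[i, "X"]))[["y1"]]
    expect_equal(s[i], want, tolerance = 1e-12)
  }
})

test_that("naive Bayes scores drift to the prior for an uninformative predictor", {
  vars <- make_vars(c("X", "Y"), c(2L, 2L))
  set.seed(3)
  n <- 20000
  y <- sample(1:2, n, TRUE, prob = c(0.3, 0.7))
  x <- sample(1:2, n, TRUE)
  d <- bn_dataset(vars, cbind(X = x, Y = y))
  s <- naive_bayes_fit_predict(d, d, "Y", positive = "y1")
  expect_lt(max(abs(s - mean(y == 1L))), 0.02)
})

test_that("ridge logistic matches an independent optimiser on a fixture", {
  vars <- make_vars(c("X", "Y"), c(2L, 2L))
  x <- cbind(X = c(1L, 1L, 1L, 2L, 2L, 2L), Y = c(1L, 1L, 2L, 1L, 2L, 2L))
  d <- bn_dataset(vars, x)
  ridge <- 0.1
  s <- logistic_fit_predict(d, d, "Y", positive = "y1", ridge = ridge)
  # independent route: BFGS on the penalised negative log-likelihood
  X <- cbind(1, as.numeric(x[, "X"] == 2L))
  y <- as.numeric(x[, "Y"] == 1L)
  nll <- function(b) {
    eta <- X %*% b
    -sum(y * eta - log1p(exp(eta))) + ridge * b[2]^2 / 2
  }
  fit <- stats::optim(c(0, 0), nll, method = "BFGS",
                      control = list(reltol = 1e-14))
  want <- stats::plogis(drop(X %*% fit$par))
  expect_equal(s, want, tolerance = 1e-4)
})

test_that("the ridge penalty shrinks towards the intercept-only rate", {
  vars <- make_vars(c("X", "Y"), c(2L, 2L))
  set.seed(4)
  n <- 400
  x <- sample(1:2, n, TRUE)
  y <- ifelse(stats::runif(n) < ifelse(x == 1, 0.8, 0.2), 1L, 2L)
  d <- bn_dataset(vars, cbind(X = x, Y = y))
  s_small <- logistic_fit_predict(d, d, "Y", positive = "y1", ridge = 0.01)
  s_huge <- logistic_fit_predict(d, d, "Y", positive = "y1", ridge = 1e7)
  expect_gt(diff(range(s_small)), 0.3)
  expect_lt(diff(range(s_huge)), 0.01)
  expect_lt(abs(mean(s_huge) - mean(y == 1L)), 0.01)
  # separable data still yields finite, monotone scores
  ds <- bn_dataset(vars, cbind(X = c(1L, 1L, 2L, 2L), Y = c(1L, 1L, 2L, 2L)))
  ss <- logistic_fit_predict(ds, ds, "Y", positive = "y1", ridge = 0.5)
  expect_true(all(is.finite(ss)))
  expect_gt(ss[1], ss[3])
})

test_that("cross-validation is seeded, reports coherent summaries, and sits at chance for pure noise", {
  vars <- make_vars(c("X1", "X2", "Y"), c(2L, 3L, 2L))
  set.seed(5)
  n <- 2000
  d <- bn_dataset(vars, cbind(X1 = sample(1:2, n, TRUE),
                              X2 = sample(1:3, n, TRUE),
                              Y = sample(1:2, n, TRUE, prob = c(0.33, 0.67))))
  dag <- bn_dag(c("X1", "X2", "Y"), rbind(c("X1", "Y")))
  rep1 <- cross_validate(d, dag, "Y", k = 5, seed = 6, positive = "y1")
  rep2 <- cross_validate(d, dag, "Y", k = 5, seed = 6, positive = "y1")
  expect_equal(rep1$per_fold, rep2$per_fold)
  expect_equal(rep1$mean_auc, mean(rep1$per_fold$auc))
  expect_equal(rep1$sd_auc, stats::sd(rep1$per_fold$auc))
  expect_lt(abs(rep1$mean_auc - 0.5), 3 * rep1$sd_auc + 0.05)
  expect_s3_class(rep1$dag_final, "bn_dag")
  expect_true(is.finite(rep1$log_score_final))
})

test_that("a function learner runs per fold and failures carry the fold id", {
  vars <- make_vars(c("A", "B"), c(2L, 2L))
  net <- make_net(vars, rbind(c("A", "B")), list(
    A = c(0.4, 0.6), B = rbind(c(0.9, 0.1), c(0.2, 0.8))))
  d <- sample_cohort(net, 600, seed = 7)
  rep <- cross_validate(d, function(train) k2_search(train, c("A", "B")),
                        "B", k = 3, seed = 8, positive = "b1")
  expect_gt(rep$mean_auc, 0.6)
  expect_error(
    cross_validate(d, function(train) stop("boom"), "B", k = 3, seed = 8),
    "fold 1")
})

test_that("excluding a variable from the evidence changes the query", {
  vars <- make_vars(c("T", "S"), c(2L, 2L))
  net <- make_net(vars, rbind(c("T", "S")), list(
    T = c(0.5, 0.5), S = rbind(c(0.9, 0.1), c(0.2, 0.8))))
  d <- sample_cohort(net, 500, seed = 9)
  dag <- net$dag
  with_t <- cross_validate(d, dag, "S", k = 2, seed = 10, positive = "s1")
  no_t <- cross_validate(d, dag, "S", k = 2, seed = 10, positive = "s1",
                         exclude = "T")
  expect_gt(with_t$mean_auc, no_t$mean_auc)
})

test_that("the missingness experiment reports both baselines per fold", {
  cfg <- generator_config()
  net <- build_truth_net(cfg)
  d <- apply_nmar(sample_cohort(net, 3000, seed = 11), cfg, seed = 12)
  tab <- missingness_experiment(d, "Survival", k = 4, seed = 13)
  expect_setequal(tab$method, c("naive_bayes", "logistic"))
  expect_true(all(tab$mean_auc > 0 & tab$mean_auc < 1))
  # the indicator design is exactly the mask over the predictors
  ind <- indicator_matrix(d, "Survival")
  pred <- setdiff(dataset_variables(d), "Survival")
  expect_equal(unname(ind$x[, pred] - 1L), unname(d$mask[, pred]))
  expect_warning(
    missingness_experiment(sample_cohort(net, 200, seed = 14), "Survival",
                           k = 2, seed = 15),
    "no missingness")
})
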