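# Stratified cross-validation, AUC/accuracy metrics, baseline classifiers
# and the missingness-informativeness experiment.

#' Stratified k-fold partition
#'
#' Splits record indices into `k` folds of near-equal size whose outcome
#' prevalence tracks the global rate (each class is dealt round-robin after
#' a seeded shuffle). Deterministic given the seed.
#'
#' @param data A [bn_dataset()].
#' @param k Number of folds (>= 2).
#' @param outcome Name of the (observed) outcome variable to stratify on.
#' @param seed RNG seed.
#' @return List of `k` integer index vectors.
#' @export
stratified_folds <- function(data, k, outcome, seed = 1L) {
  n <- nrow(data$x)
  if (k < 2L || k > n) stop_usage("k must lie in [2, n]")
  oj <- match(outcome, var_names(data))
  if (is.na(oj)) stop_usage("unknown outcome column: ", outcome)
  if (any(data$mask[, oj] == 0L))
    stop_usage("outcome must be observed for every record")
  y <- data$x[, oj]
  with_seed(seed, {
    fold <- integer(n)
    offset <- 0L
    for (cls in sort(unique(y))) {
      idx <- sample(which(y == cls))
      fold[idx] <- ((seq_along(idx) + offset - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
    lapply(seq_len(k), function(f) which(fold == f))
  })
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a uniformly chosen positive outranks a uniformly
#' chosen negative, with ties counted one half; computed from midranks.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1 or logical), 1 = positive.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop_usage("length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_usage("AUC is undefined with a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

accuracy_at_half <- function(scores, labels) {
  mean((scores >= 0.5) == (as.integer(labels) == 1L))
}

#' Naive Bayes fit-and-predict
#'
#' `P(outcome | x)` proportional to `P(outcome) * prod_i P(x_i | outcome)`
#' with the same uniform-Dirichlet smoothing as [fit_parameters()]; it is
#' exactly the posterior of the star-shaped network with the outcome as the
#' single parent of every predictor.
#'
#' @param train,test [bn_dataset()]s over the same variables.
#' @param outcome Outcome variable name.
#' @param positive Outcome state scored (default the first state).
#' @param pseudocount Dirichlet pseudocount.
#' @return Numeric vector of `P(outcome = positive | x)` for the test rows.
#' @export
naive_bayes_fit_predict <- function(train, test, outcome,
                                    positive = NULL, pseudocount = 1) {
  nm <- var_names(train)
  star <- bn_dag(nm, cbind(outcome, setdiff(nm, outcome)))
  net <- fit_parameters(star, train, pseudocount)
  states <- train$variables[[outcome]]$states
  positive <- positive %||% states[1L]
  p <- predict_posterior(net, test, outcome)
  unname(p[, positive])
}

#' Ridge-penalised logistic regression fit-and-predict
#'
#' Predictors are one-hot encoded from their categories (first state as the
#' reference level) and an L2-penalised logistic model is fitted by Newton
#' iterations to a gradient norm below `1e-6`; the intercept is not
#' penalised. The penalty keeps the solution finite on separable data.
#'
#' @param train,test [bn_dataset()]s over the same variables.
#' @param outcome Outcome variable name (binary).
#' @param positive Outcome state modelled as 1 (default the first state).
#' @param ridge Non-negative L2 penalty.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return Numeric vector of predicted `P(outcome = positive | x)`.
#' @export
logistic_fit_predict <- function(train, test, outcome, positive = NULL,
                                 ridge = 1, max_iter = 100L) {
  if (ridge < 0) stop_usage("ridge must be non-negative")
  nm <- var_names(train)
  states <- train$variables[[outcome]]$states
  if (length(states) != 2L) stop_usage("outcome must be binary")
  positive <- positive %||% states[1L]
  y <- as.numeric(train$x[, match(outcome, nm)] == match(positive, states))
  one_hot <- function(data) {
    preds <- setdiff(nm, outcome)
    cols <- lapply(preds, function(v) {
      r <- length(data$variables[[v]]$states)
      if (r < 2L) return(NULL)
      vals <- data$x[, match(v, nm)]
      m <- matrix(0, nrow(data$x), r - 1L)
      for (s in 2:r) m[, s - 1L] <- as.numeric(vals == s)
      colnames(m) <- paste0(v, "=", data$variables[[v]]$states[2:r])
      m
    })
    cbind(`(Intercept)` = 1, do.call(cbind, cols))
  }
  X <- one_hot(train)
  Xt <- one_hot(test)
  d <- ncol(X)
  pen <- c(0, rep(ridge, d - 1L))  # intercept unpenalised
  beta <- numeric(d)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    g <- drop(crossprod(X, y - p)) - pen * beta
    if (sqrt(sum(g^2)) < 1e-6) { converged <- TRUE; break }
    wts <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X * wts, X) + diag(pen, d)
    step <- solve(H, g)
    # step halving against divergence of the penalised log-likelihood
    obj <- function(b) {
      e <- drop(X %*% b)
      sum(y * e - log1p(exp(e))) - sum(pen * b^2) / 2
    }
    f0 <- obj(beta)
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      if (obj(cand) >= f0 - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    beta <- beta + lambda * step
  }
  if (!converged) {
    eta <- drop(X %*% beta)
    g <- drop(crossprod(X, y - stats::plogis(eta))) - pen * beta
    if (sqrt(sum(g^2)) >= 1e-6)
      stop_usage("logistic fit did not converge in ", max_iter,
                 " iterations (gradient norm ", format(sqrt(sum(g^2))), ")")
  }
  unname(stats::plogis(drop(Xt %*% beta)))
}

#' Cross-validated structure learning and survival prediction
#'
#' The experimental harness: for each stratified fold, learn a structure on
#' the other folds (or use a fixed structure), fit CPTs with the uniform
#' Dirichlet prior, and score the held-out records by the posterior of the
#' outcome given every other recorded variable (the explicit-missingness
#' encoding makes all records complete, so missingness itself is evidence).
#' AUC and accuracy (at a 0.5 threshold) are reported per fold; the fold
#' structures are then aggregated into a final DAG by [aggregate_dags()] and
#' that DAG's Bayesian score on the full dataset is attached.
#'
#' @param data A [bn_dataset()].
#' @param learner Either a fixed [bn_dag()] or a function
#'   `function(train) -> bn_dag`.
#' @param outcome Binary outcome variable name.
#' @param k Number of folds (default 10).
#' @param seed Seed controlling the fold partition.
#' @param positive Outcome state treated as positive (default first state).
#' @param pseudocount Dirichlet pseudocount for CPT fitting.
#' @param exclude Optional character vector of variables to drop from the
#'   evidence at prediction time (e.g. the treatment variable); they still
#'   participate in structure and parameter learning.
#' @return An object of class `bn_cv_report`.
#' @export
cross_validate <- function(data, learner, outcome, k = 10L, seed = 1L,
                           positive = NULL, pseudocount = 1,
                           exclude = NULL) {
  nm <- var_names(data)
  states <- data$variables[[outcome]]$states
  positive <- positive %||% states[1L]
  pos_idx <- match(positive, states)
  if (is.na(pos_idx)) stop_usage("unknown positive state: ", positive)
  folds <- stratified_folds(data, k, outcome, seed)
  learn <- if (inherits(learner, "bn_dag")) {
    function(train) learner
  } else if (is.function(learner)) {
    learner
  } else stop_usage("learner must be a bn_dag or a function(train) -> bn_dag")
  per_fold <- vector("list", k)
  dags <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train <- dataset_rows(data, setdiff(seq_len(nrow(data$x)), test_idx))
    test <- dataset_rows(data, test_idx)
    dag <- tryCatch(learn(train), error = function(e)
      stop_usage("structure learner failed on fold ", f, ": ",
                 conditionMessage(e)))
    net <- fit_parameters(dag, train, pseudocount)
    scores <- if (is.null(exclude)) {
      predict_posterior(net, test, outcome)[, pos_idx]
    } else {
      vapply(seq_len(nrow(test$x)), function(i) {
        ev_vars <- setdiff(nm, c(outcome, exclude))
        ev <- stats::setNames(as.list(test$x[i, ev_vars]), ev_vars)
        posterior(net, outcome, ev)[[pos_idx]]
      }, 0)
    }
    y <- as.integer(test$x[, match(outcome, nm)] == pos_idx)
    per_fold[[f]] <- data.frame(fold = f, auc = auc(scores, y),
                                accuracy = accuracy_at_half(scores, y))
    dags[[f]] <- dag
  }
  per_fold <- do.call(rbind, per_fold)
  dag_final <- aggregate_dags(dags)
  report <- list(per_fold = per_fold, fold_dags = dags,
                 mean_auc = mean(per_fold$auc), sd_auc = stats::sd(per_fold$auc),
                 mean_accuracy = mean(per_fold$accuracy),
                 sd_accuracy = stats::sd(per_fold$accuracy),
                 dag_final = dag_final,
                 log_score_final = log_bayesian_score(dag_final, data),
                 k = k, seed = seed, outcome = outcome, positive = positive)
  class(report) <- "bn_cv_report"
  report
}

#' @export
print.bn_cv_report <- function(x, ...) {
  cat(sprintf("<bn_cv_report> %d-fold CV on '%s'\n", x$k, x$outcome))
  cat(sprintf("  AUC      %.3f (+/- %.3f)\n", x$mean_auc, x$sd_auc))
  cat(sprintf("  Accuracy %.2f%% (+/- %.2f)\n", 100 * x$mean_accuracy,
              100 * x$sd_accuracy))
  cat(sprintf("  log Bayesian score (final DAG): %.1f\n", x$log_score_final))
  invisible(x)
}

#' Does missingness alone predict survival?
#'
#' Replaces every predictor by its binary observedness indicator
#' ([indicator_matrix()]) and cross-validates the Naive Bayes and ridge
#' logistic baselines on the indicators. Informative (NMAR) missingness
#' shows up as AUC clearly above chance; under MCAR both hover at 0.5.
#'
#' @param data A [bn_dataset()] with a missingness mask.
#' @param outcome Binary outcome variable name (fully observed).
#' @param k Folds (default 10).
#' @param seed Fold seed.
#' @param positive Positive outcome state.
#' @param ridge L2 penalty for the logistic baseline.
#' @return Data frame with one row per method: mean/sd AUC and accuracy.
#' @export
missingness_experiment <- function(data, outcome, k = 10L, seed = 1L,
                                   positive = NULL, ridge = 1) {
  if (all(data$mask == 1L))
    warning("dataset has no missingness; indicator AUC will be at chance")
  ind <- indicator_matrix(data, outcome)
  states <- ind$variables[[outcome]]$states
  positive <- positive %||% states[1L]
  pos_idx <- match(positive, states)
  folds <- stratified_folds(ind, k, outcome, seed)
  nm <- var_names(ind)
  run <- function(predict_fun) {
    res <- lapply(seq_len(k), function(f) {
      train <- dataset_rows(ind, setdiff(seq_len(nrow(ind$x)), folds[[f]]))
      test <- dataset_rows(ind, folds[[f]])
      scores <- predict_fun(train, test)
      y <- as.integer(test$x[, match(outcome, nm)] == pos_idx)
      c(auc = auc(scores, y), accuracy = accuracy_at_half(scores, y))
    })
    m <- do.call(rbind, res)
    c(mean_auc = mean(m[, "auc"]), sd_auc = stats::sd(m[, "auc"]),
      mean_accuracy = mean(m[, "accuracy"]),
      sd_accuracy = stats::sd(m[, "accuracy"]))
  }
  nb <- run(function(train, test)
    naive_bayes_fit_predict(train, test, outcome, positive))
  lr <- run(function(train, test)
    logistic_fit_predict(train, test, outcome, positive, ridge))
  out <- as.data.frame(rbind(naive_bayes = nb, logistic = lr))
  out$method <- rownames(out)
  rownames(out) <- NULL
  out[, c("method", "mean_auc", "sd_auc", "mean_accuracy", "sd_accuracy")]
}
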