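# Synthetic registry-like cohorts from a configurable ground-truth Bayesian
# network. The generator emulates the published facts about the cohort (13
# clinical variables and their state spaces, a 1-year survival prior of
# 0.33, the treatment-plan frequency table, ~32% informative missingness);
# the cross-variable dependence strengths are documented defaults, not
# estimates of any real registry.

#' The 13 default clinical variables
#'
#' Age, FEV1 absolute and percentage, performance status, comorbidity
#' count, staging identifier, primary diagnosis (ICD-10), laterality, TNM
#' category, histology (SNOMED), site-specific stage, suggested treatment
#' plan and 1-year survival, with their category lists and temporal tiers.
#'
#' @return Named list of [variable_spec()]s.
#' @export
default_variables <- function() {
  v <- list(
    variable_spec("Age", c("<50", "50-60", "60-70", "70-80", ">80")),
    variable_spec("StagingID", c("6", "7")),
    variable_spec("FEV1Abs", c("<1.0", "1-1.5", "1.5-2.0", ">2.0")),
    variable_spec("FEV1Perc", c("<30", "30-40", "40-80", ">80")),
    variable_spec("PerformanceStatus", c("0", "1", "2", "3", "4")),
    variable_spec("Comorbidities", c("0", "1", "2", "3", "4", "5")),
    variable_spec("Diagnosis", c("C33", "C34", "C34.0", "C34.1", "C34.2",
                                 "C34.3", "C34.8", "C34.9", "C38.4",
                                 "C38.3", "C38.8")),
    variable_spec("Laterality", c("Left", "Right", "Midline", "Bilateral",
                                  "Not Applicable")),
    variable_spec("TNMCategory", c("IA", "IB", "IIA", "IIB", "IIIA", "IIIB",
                                   "IV", "Uncertain")),
    variable_spec("Histology", c("M8010/2", "M8041/3", "M8046/3", "M8070/3",
                                 "M8140/3", "M8250/3", "M8012/3", "M8020/3",
                                 "M8013/3", "M8240", "M8980/3", "M8940/3",
                                 "M9999/9")),
    variable_spec("SiteStage", c("Limited", "Extensive", "Unknown")),
    variable_spec("Treatment", c("1", "2", "3", "5", "6", "7", "8", "9",
                                 "10", "11", "Null"), tier = "treatment"),
    variable_spec("Survival", c("Alive", "Dead"), tier = "post_treatment"))
  names(v) <- vapply(v, `[[`, "", "name")
  v
}

#' Default tier-respecting ground-truth structure
#'
#' Hand-authored topology: dependencies among the pre-treatment variables,
#' clinical-eligibility-style parents for the treatment decision (TNM stage
#' and performance status), and direct pre-treatment influences plus the
#' treatment itself as parents of survival. No edge points backwards in
#' time.
#'
#' @return A [bn_dag()].
#' @export
default_truth_dag <- function() {
  bn_dag(names(default_variables()), rbind(
    c("Age", "Comorbidities"),
    c("Age", "PerformanceStatus"),
    c("Comorbidities", "PerformanceStatus"),
    c("Age", "FEV1Abs"),
    c("FEV1Abs", "FEV1Perc"),
    c("Histology", "Diagnosis"),
    c("Histology", "SiteStage"),
    c("Histology", "TNMCategory"),
    c("StagingID", "TNMCategory"),
    c("Diagnosis", "Laterality"),
    c("TNMCategory", "Treatment"),
    c("PerformanceStatus", "Treatment"),
    c("Treatment", "Survival"),
    c("TNMCategory", "Survival"),
    c("PerformanceStatus", "Survival"),
    c("Age", "Survival")))
}

#' A deliberately degraded "manual" structure
#'
#' Mimics a clinician-elicited graph that misattributes the drivers of
#' survival: relative to [default_truth_dag()], four edges are rewired (the
#' strong TNM/performance/age parents of survival and the TNM parent of
#' treatment are replaced by weakly informative ones). Used as the
#' comparison arm in the structure-ranking experiments.
#'
#' @return A [bn_dag()].
#' @export
default_misspecified_dag <- function() {
  truth <- default_truth_dag()
  e <- dag_edges(truth)
  deleted <- rbind(c("TNMCategory", "Survival"),
                   c("PerformanceStatus", "Survival"),
                   c("Age", "Survival"),
                   c("TNMCategory", "Treatment"))
  keep <- !(paste(e$from, e$to) %in% paste(deleted[, 1L], deleted[, 2L]))
  added <- rbind(c("StagingID", "Survival"),
                 c("Laterality", "Survival"),
                 c("Comorbidities", "Survival"),
                 c("Age", "Treatment"))
  bn_dag(truth$nodes, rbind(as.matrix(e[keep, ]), added))
}

#' Generator configuration
#'
#' Bundles the ground-truth structure with the calibration targets: the
#' 1-year survival prior, the treatment-plan marginal frequencies (which
#' include a mass of unrecorded "Null" plans), the overall missingness rate
#' and the strength of the informative-missingness mechanism.
#'
#' @param variables Variable declarations (default [default_variables()]).
#' @param truth_dag Ground-truth structure (default [default_truth_dag()]);
#'   must respect the temporal tiers.
#' @param cpt_seed Seed for the CPT construction noise.
#' @param survival_target Marginal `P(Survival = Alive)` (default 0.33).
#' @param treatment_marginals Named probability vector over treatment states
#'   summing to 1 (default: the registry frequency table).
#' @param missing_rate_target Overall fraction of deletable cells set to
#'   missing (default 0.32).
#' @param nmar_strength Logit-scale coefficient linking disease severity to
#'   the per-cell deletion probability; 0 reduces the mechanism to MCAR.
#' @return An object of class `bn_generator_config`.
#' @export
generator_config <- function(variables = default_variables(),
                             truth_dag = default_truth_dag(),
                             cpt_seed = 1L,
                             survival_target = 0.33,
                             treatment_marginals = NULL,
                             missing_rate_target = 0.32,
                             nmar_strength = 3) {
  if (is.null(treatment_marginals)) {
    treatment_marginals <- c(`1` = 10, `2` = 14.79, `3` = 19, `5` = 23,
                             `6` = 9, `7` = 7, `8` = 1, `9` = 0.08,
                             `10` = 0.13, `11` = 2, Null = 14) / 100
  }
  if (abs(sum(treatment_marginals) - 1) > 1e-9)
    stop_usage("treatment marginals must sum to 1")
  if (survival_target <= 0 || survival_target >= 1 ||
      missing_rate_target <= 0 || missing_rate_target >= 1)
    stop_usage("calibration targets must lie in (0, 1)")
  if (nmar_strength < 0) stop_usage("nmar_strength must be >= 0")
  tiers <- stats::setNames(
    c(pre_treatment = 1L, treatment = 2L,
      post_treatment = 3L)[vapply(variables, `[[`, "", "tier")],
    names(variables))
  if (tier_violations(truth_dag, tiers) > 0L)
    stop_usage("truth_dag violates the temporal tiers")
  structure(list(variables = variables, truth_dag = truth_dag,
                 cpt_seed = as.integer(cpt_seed),
                 survival_target = survival_target,
                 treatment_marginals = treatment_marginals,
                 missing_rate_target = missing_rate_target,
                 nmar_strength = nmar_strength),
            class = "bn_generator_config")
}

# Severity scores in [0, 1] used throughout the generator. The "Uncertain"
# TNM category sits mid-scale.
tnm_severity <- function(k) ifelse(k == 8L, 0.5, (k - 1) / 6)
perf_severity <- function(k) (k - 1) / 4
age_severity <- function(k) (k - 1) / 4

# Exact joint marginal over a subset of variables by factor elimination.
joint_marginal_factor <- function(net, vars) {
  res <- eliminate_to(lapply(net$cpts, factor_from_cpt), vars)
  # reorder to the requested variable order
  perm_idx <- factor_cell_index(vars,
                               res$dims[match(vars, res$vars)],
                               res$vars, res$dims)
  new_factor(vars, res$dims[match(vars, res$vars)], res$vals[perm_idx])
}

# Row-normalised probability matrix from positive weights.
normalise_rows <- function(w) w / rowSums(w)

build_cpt_from_weights <- function(child, parents, variables, weights) {
  new_cpt(child, parents, variables[[child]]$states,
          lapply(parents, function(p) variables[[p]]$states),
          normalise_rows(weights), NA_real_)
}

# Per-node weight recipes. Each recipe maps an assignment of the node's
# *actual* parents (a one-row list; entries may be absent when the
# configured structure drops an edge, in which case a neutral mid-scale
# value stands in) to an unnormalised weight vector over the node's states.
# Severity terms: older age, higher TNM stage and worse performance status
# depress lung function and survival and steer treatment eligibility.
node_recipe <- function(v, a, vars, cfg) {
  sclc_hist <- c("M8041/3", "M8046/3", "M8013/3")
  sev_or <- function(val, f, neutral = 0.5) if (is.null(val)) neutral else f(val)
  switch(v,
    Age = c(0.08, 0.17, 0.28, 0.30, 0.17),
    StagingID = c(0.45, 0.55),
    Comorbidities = {
      lambda <- 0.8 + 1.8 * sev_or(a$Age, age_severity)
      stats::dpois(0:5, lambda) + 1e-4
    },
    PerformanceStatus = {
      mu <- 4 * (0.5 * sev_or(a$Age, age_severity) +
                 0.5 * sev_or(a$Comorbidities, function(k) (k - 1) / 5))
      exp(-0.8 * ((0:4) - mu)^2) + 1e-4
    },
    FEV1Abs = {
      mu <- 3.2 - 1.6 * sev_or(a$Age, age_severity)
      exp(-0.7 * ((1:4) - mu)^2) + 1e-4
    },
    FEV1Perc = {
      mu <- if (is.null(a$FEV1Abs)) 2.5 else a$FEV1Abs
      exp(-0.8 * ((1:4) - mu)^2) + 1e-4
    },
    Histology = c(0.04, 0.16, 0.03, 0.20, 0.22, 0.04, 0.02, 0.05,
                  0.06, 0.02, 0.01, 0.02, 0.13),
    Diagnosis = c(0.02, 0.10, 0.06, 0.16, 0.08, 0.14, 0.05, 0.33,
                  0.02, 0.02, 0.02),
    TNMCategory = {
      sclc <- sev_or(a$Histology,
                     function(h) as.numeric(vars$Histology$states[h] %in% sclc_hist),
                     neutral = 0.2)
      staging <- sev_or(a$StagingID, function(s) s - 1)
      mu <- 4.2 + 1.6 * sclc + 0.3 * staging
      stage <- exp(-0.28 * ((1:7) - mu)^2)
      c(stage / sum(stage) * 0.92, 0.08)
    },
    SiteStage = {
      sclc <- sev_or(a$Histology,
                     function(h) as.numeric(vars$Histology$states[h] %in% sclc_hist),
                     neutral = 0.2)
      sclc * c(0.40, 0.45, 0.15) + (1 - sclc) * c(0.03, 0.04, 0.93)
    },
    Laterality = c(0.42, 0.46, 0.04, 0.03, 0.05),
    Treatment = {
      tnm <- sev_or(a$TNMCategory, tnm_severity)
      perf <- sev_or(a$PerformanceStatus, perf_severity)
      mod <- c(`1` = exp(-6 * tnm - 3 * perf),
               `2` = exp(1.0 * tnm - 0.5 * perf),
               `3` = exp(1.5 * tnm - 1.0 * perf),
               `5` = exp(3.0 * tnm + 1.8 * perf),
               `6` = exp(1.5 * perf - 1.5 * tnm),
               `7` = exp(0.6 * tnm - 0.8 * perf),
               `8` = exp(0.6 * tnm - 1.2 * perf),
               `9` = exp(-5 * tnm - 2.5 * perf),
               `10` = exp(-5 * tnm - 2.5 * perf),
               `11` = exp(-5.5 * tnm - 3 * perf),
               Null = 1)
      tstates <- vars$Treatment$states
      unname(cfg$treatment_marginals[tstates] * mod[tstates])
    },
    stop_usage("no generator recipe for variable '", v, "'"))
}

# Logit of 1-year survival before the calibrated intercept; terms only for
# the parents the configured structure actually contains.
survival_logit <- function(a, vars) {
  lift <- c(`1` = 1.8, `2` = 0.4, `3` = 0.5, `5` = -0.8, `6` = 0.2,
            `7` = 1.0, `8` = 1.1, `9` = 1.85, `10` = 1.9, `11` = 2.0,
            Null = -0.4)
  out <- 0
  if (!is.null(a$Treatment))
    out <- out + lift[vars$Treatment$states[a$Treatment]]
  if (!is.null(a$TNMCategory)) out <- out - 3.2 * tnm_severity(a$TNMCategory)
  if (!is.null(a$PerformanceStatus))
    out <- out - 1.6 * perf_severity(a$PerformanceStatus)
  if (!is.null(a$Age)) out <- out - 0.8 * age_severity(a$Age)
  unname(out)
}

#' Build the calibrated ground-truth network
#'
#' Constructs one structured CPT per variable over the parent set the
#' configured structure prescribes (disease severity drives performance,
#' stage, treatment eligibility and survival; a small seeded logit-scale
#' jitter makes every table generic), then calibrates: the treatment CPT is
#' scaled column-wise (with row renormalisation) until the exact treatment
#' marginals match the configured frequencies, and the survival CPT's
#' intercept is solved with `uniroot` so that the exact
#' `P(Survival = Alive)` equals the survival target. Both marginals are
#' verified by exact elimination; the build fails if calibration does not
#' converge.
#'
#' Treatment assignment follows clinical eligibility (stage and performance
#' status), *not* survival maximisation, while surgical plans carry the
#' largest survival lift; this gives the cohort the qualitative signature
#' the concordance analysis is designed to detect.
#'
#' @param cfg A [generator_config()].
#' @param max_iter Iteration cap for the treatment-marginal calibration.
#' @return A `bn_fit` ground-truth network (deterministic given
#'   `cfg$cpt_seed`).
#' @export
build_truth_net <- function(cfg = generator_config(), max_iter = 500L) {
  stopifnot(inherits(cfg, "bn_generator_config"))
  vars <- cfg$variables
  dag <- cfg$truth_dag
  with_seed(cfg$cpt_seed, {
    jitter <- function(w, sd = 0.15) exp(log(w) + stats::rnorm(length(w), 0, sd))
    grid <- function(parents) {
      g <- expand.grid(lapply(parents, function(p)
        seq_along(vars[[p]]$states)), KEEP.OUT.ATTRS = FALSE)
      names(g) <- parents
      g
    }
    recipe_rows <- function(v, parents, sd = 0.15) {
      g <- grid(parents)
      r <- length(vars[[v]]$states)
      n_cfg <- max(nrow(g), 1L)
      w <- matrix(0, n_cfg, r)
      for (i in seq_len(n_cfg)) {
        a <- if (length(parents)) as.list(g[i, parents, drop = FALSE]) else list()
        w[i, ] <- jitter(node_recipe(v, a, vars, cfg), sd)
      }
      w
    }
    cpts <- list()
    for (v in setdiff(topological_order(dag), c("Treatment", "Survival"))) {
      pa <- dag_parents(dag, v)
      cpts[[v]] <- build_cpt_from_weights(v, pa, vars, recipe_rows(v, pa))
    }
    # --- treatment: eligibility-style, calibrated to the marginals ------
    tstates <- vars$Treatment$states
    pa_treat <- dag_parents(dag, "Treatment")
    treat_prob <- normalise_rows(recipe_rows("Treatment", pa_treat, sd = 0.1))
    pre_nodes <- setdiff(dag$nodes, c("Treatment", "Survival"))
    pre_edges <- dag_edges(dag)
    pre_edges <- pre_edges[pre_edges$from %in% pre_nodes &
                             pre_edges$to %in% pre_nodes, ]
    pre_net <- structure(list(
      dag = bn_dag(pre_nodes, as.matrix(pre_edges)),
      cpts = cpts[pre_nodes], variables = vars[pre_nodes]),
      class = "bn_fit")
    w_pa <- if (length(pa_treat))
      joint_marginal_factor(pre_net, pa_treat)$vals else 1
    target <- cfg$treatment_marginals[tstates]
    for (it in seq_len(max_iter)) {
      marg <- drop(crossprod(treat_prob, w_pa))
      if (max(abs(marg - target)) < 1e-4) break
      treat_prob <- normalise_rows(treat_prob *
                                     rep(target / marg, each = nrow(treat_prob)))
    }
    marg <- drop(crossprod(treat_prob, w_pa))
    if (max(abs(marg - target)) > 0.01)
      stop_usage("treatment marginal calibration did not converge; achieved: ",
                 paste(sprintf("%s=%.3f", tstates, marg), collapse = ", "))
    cpts$Treatment <- build_cpt_from_weights("Treatment", pa_treat, vars,
                                             treat_prob)
    # --- survival: logistic in severity + treatment lift, intercept solved
    # for the marginal target --------------------------------------------
    pa_surv <- dag_parents(dag, "Survival")
    gs <- grid(pa_surv)
    n_cfg <- max(nrow(gs), 1L)
    base_logit <- vapply(seq_len(n_cfg), function(i) {
      a <- if (length(pa_surv)) as.list(gs[i, pa_surv, drop = FALSE]) else list()
      survival_logit(a, vars)
    }, 0) + stats::rnorm(n_cfg, 0, 0.15)
    rest_nodes <- setdiff(dag$nodes, "Survival")
    rest_edges <- dag_edges(dag)
    rest_edges <- rest_edges[rest_edges$to != "Survival", ]
    surv_net <- structure(list(
      dag = bn_dag(rest_nodes, as.matrix(rest_edges)),
      cpts = cpts[rest_nodes], variables = vars[rest_nodes]),
      class = "bn_fit")
    w_pa_s <- if (length(pa_surv))
      joint_marginal_factor(surv_net, pa_surv)$vals else 1
    target_s <- cfg$survival_target
    root <- stats::uniroot(function(b0)
      sum(w_pa_s * stats::plogis(b0 + base_logit)) - target_s,
      interval = c(-15, 15), tol = 1e-10)
    p_alive <- stats::plogis(root$root + base_logit)
    cpts$Survival <- build_cpt_from_weights("Survival", pa_surv, vars,
                                            cbind(p_alive, 1 - p_alive))
    achieved <- sum(w_pa_s * p_alive)
    if (abs(achieved - target_s) > 0.005)
      stop_usage("survival calibration did not converge; achieved ",
                 sprintf("%.4f", achieved))
    net <- structure(list(dag = dag, cpts = cpts[dag$nodes],
                          variables = vars[dag$nodes]),
                     class = "bn_fit")
    attr(net, "config") <- cfg
    attr(net, "survival_marginal") <- achieved
    attr(net, "treatment_marginal") <- stats::setNames(marg, tstates)
    net
  })
}

#' Sample a complete cohort from a network
#'
#' Ancestral sampling in topological order; deterministic given the seed.
#'
#' @param net A `bn_fit`.
#' @param n Number of records.
#' @param seed RNG seed.
#' @return A fully observed [bn_dataset()].
#' @export
sample_cohort <- function(net, n, seed = 1L) {
  if (n < 1L) stop_usage("n must be >= 1")
  nodes <- net$dag$nodes
  cds <- net_cards(net)
  with_seed(seed, {
    x <- matrix(0L, n, length(nodes), dimnames = list(NULL, nodes))
    for (v in topological_order(net$dag)) {
      cpt <- net$cpts[[v]]
      r <- length(cpt$states)
      cum <- t(apply(cpt$prob, 1L, cumsum))
      if (!length(cpt$parents)) {
        j <- rep.int(1L, n)
      } else {
        j <- parent_config_index(x, match(cpt$parents, nodes), cds)
      }
      u <- stats::runif(n)
      x[, v] <- 1L + rowSums(cum[j, -r, drop = FALSE] < u)
    }
    bn_dataset(net$variables[nodes], x)
  })
}

#' Delete cells via the informative (NMAR) missingness mechanism
#'
#' Each pre-treatment cell of a record is deleted independently with a
#' probability that is logistic in the record's latent disease-severity
#' proxy (its TNM stage and performance status), scaled by
#' `cfg$nmar_strength`; the intercept is solved so the expected overall
#' deletion fraction over deletable cells equals `cfg$missing_rate_target`.
#' With strength 0 the mechanism is MCAR at the target rate. The treatment
#' and outcome columns are never deleted. Deleted cells receive the
#' explicit sentinel state and `mask = 0`.
#'
#' @param data A complete [bn_dataset()] (as from [sample_cohort()]).
#' @param cfg The [generator_config()].
#' @param seed RNG seed.
#' @return A [bn_dataset()] with sentinel states appended to the deletable
#'   variables and the mask recording the deletions.
#' @export
apply_nmar <- function(data, cfg = generator_config(), seed = 1L) {
  if (any(data$mask == 0L)) stop_usage("apply_nmar needs a complete dataset")
  nm <- var_names(data)
  deletable <- nm[tiers_of(data) == "pre_treatment"]
  sev <- 0.6 * tnm_severity(data$x[, "TNMCategory"]) +
    0.4 * perf_severity(data$x[, "PerformanceStatus"])
  s <- cfg$nmar_strength
  target <- cfg$missing_rate_target
  f <- function(a) mean(stats::plogis(a + s * (sev - mean(sev)))) - target
  if (f(-30) > 0 || f(30) < 0)
    stop_usage("missingness target infeasible under the mechanism")
  a <- stats::uniroot(f, interval = c(-30, 30), tol = 1e-10)$root
  p_del <- stats::plogis(a + s * (sev - mean(sev)))
  with_seed(seed, {
    n <- nrow(data$x)
    variables <- data$variables
    x <- data$x
    mask <- data$mask
    for (v in deletable) {
      hit <- stats::runif(n) < p_del
      if (!any(hit)) next
      variables[[v]] <- add_missing_state(variables[[v]])
      x[hit, v] <- length(variables[[v]]$states)
      mask[hit, v] <- 0L
    }
    out <- bn_dataset(variables, x, mask)
    attr(out, "missing_fraction") <-
      mean(mask[, deletable] == 0L)
    out
  })
}
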