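# Treatment plans, survival-maximising recommendation and concordance
# analysis.

#' The registry treatment plan catalogue
#'
#' The ten coded treatment plans with their modality composition. Palliative
#' care (5) and active monitoring (6) are the non-curative plans; plans 1,
#' 9, 10 and 11 involve surgical resection; 2, 3, 7 and 8 are chemotherapy
#' and/or radiotherapy.
#'
#' @return Data frame with columns `code`, `label`, `curative` and a
#'   `modalities` list column (subsets of surgery/chemo/radio/palliative/
#'   monitoring).
#' @export
treatment_plans <- function() {
  plans <- data.frame(
    code = c(1L, 2L, 3L, 5L, 6L, 7L, 8L, 9L, 10L, 11L),
    label = c("Surgery", "Radiotherapy", "Chemotherapy", "Palliative care",
              "Active Monitoring",
              "Sequential chemotherapy and radiotherapy",
              "Concurrent chemotherapy and radiotherapy",
              "Induction chemotherapy to downstage before surgery",
              "Neo-adjuvant chemotherapy and surgery",
              "Surgery followed by adjuvant chemotherapy"),
    curative = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  plans$modalities <- list(
    "surgery", "radio", "chemo", "palliative", "monitoring",
    c("chemo", "radio"), c("chemo", "radio"),
    c("chemo", "surgery"), c("chemo", "surgery"), c("surgery", "chemo"))
  plans
}

#' Codes of the curative treatment plans
#' @return Integer vector.
#' @export
curative_codes <- function() treatment_plans()$code[treatment_plans()$curative]

#' Codes of the surgical treatment plans
#' @return Integer vector.
#' @export
surgical_codes <- function() c(1L, 9L, 10L, 11L)

plan_row <- function(code) {
  plans <- treatment_plans()
  i <- match(as.integer(code), plans$code)
  if (is.na(i)) stop_usage("unknown treatment code: ", code)
  plans[i, ]
}

#' Concordance level between two treatment plans
#'
#' `"exact"` when the codes agree; `"partial"` when they differ but share at
#' least one treatment modality (e.g. surgery alone versus surgery followed
#' by adjuvant chemotherapy both involve surgery); `"none"` otherwise.
#'
#' @param recorded,recommended Treatment plan codes.
#' @return One of `"exact"`, `"partial"`, `"none"`.
#' @export
match_level <- function(recorded, recommended) {
  a <- plan_row(recorded); b <- plan_row(recommended)
  if (a$code == b$code) return("exact")
  if (length(intersect(a$modalities[[1L]], b$modalities[[1L]]))) return("partial")
  "none"
}

#' Select the eligible cohort for the intervention experiments
#'
#' Keeps records that (1) carry an included diagnosis, (2) received a
#' curative treatment plan and (3) have no missing data. The per-filter
#' removal counts are attached as the `"selection_log"` attribute.
#'
#' @param data A [bn_dataset()].
#' @param treatment Treatment variable name.
#' @param diagnosis Diagnosis variable name; `NULL` skips the diagnosis
#'   filter.
#' @param diagnosis_states States of `diagnosis` that are eligible.
#' @param curative States of `treatment` counting as curative; defaults to
#'   the curative plan codes as labels.
#' @return The eligible subset as a [bn_dataset()].
#' @export
select_eligible <- function(data, treatment, diagnosis = NULL,
                            diagnosis_states = NULL,
                            curative = as.character(curative_codes())) {
  nm <- var_names(data)
  keep <- rep(TRUE, nrow(data$x))
  log <- data.frame(filter = character(0), removed = integer(0))
  note <- function(label, removed)
    rbind(log, data.frame(filter = label, removed = removed))
  if (!is.null(diagnosis)) {
    if (!diagnosis %in% nm) stop_usage("unknown diagnosis column")
    states <- data$variables[[diagnosis]]$states
    ok <- data$x[, diagnosis] %in% match(diagnosis_states, states)
    log <- note("diagnosis", sum(keep & !ok)); keep <- keep & ok
  }
  if (!treatment %in% nm) stop_usage("unknown treatment column")
  tstates <- data$variables[[treatment]]$states
  idx <- match(curative, tstates)
  idx <- idx[!is.na(idx)]
  ok <- data$x[, treatment] %in% idx
  log <- note("curative_treatment", sum(keep & !ok)); keep <- keep & ok
  ok <- rowSums(data$mask == 0L) == 0L
  log <- note("complete_record", sum(keep & !ok)); keep <- keep & ok
  if (!any(keep)) stop_usage("no records pass the eligibility filters")
  out <- dataset_rows(data, keep)
  attr(out, "selection_log") <- log
  out
}

#' Survival-maximising treatment recommendation for one patient
#'
#' Ranks the candidate treatment plans by the interventional survival
#' probability `P(outcome = Alive | evidence, do(treatment = t))` and
#' recommends the argmax. Ties (within `1e-12`) are flagged and broken
#' towards the lowest treatment code so the output is deterministic.
#'
#' @param net A `bn_fit`, typically already mutilated at the treatment
#'   variable (if not, incoming edges are cut on the fly).
#' @param evidence Named list/vector of the patient's pre-treatment
#'   findings.
#' @param treatment Treatment variable name.
#' @param outcome Outcome variable name.
#' @param candidates Candidate plan codes; defaults to all curative plans
#'   (non-curative plans are excluded from intervention by design).
#' @param state Outcome state being maximised (default `"Alive"`).
#' @return An object of class `bn_recommendation`: a ranking data frame
#'   (`code`, `probability`), the top code, and a tie flag.
#' @export
recommend <- function(net, evidence, treatment, outcome,
                      candidates = curative_codes(), state = "Alive") {
  if (!length(candidates)) stop_usage("candidates must be non-empty")
  candidates <- sort(as.integer(candidates))
  net_do <- mutilate(net, treatment)
  probs <- vapply(candidates, function(code)
    interventional_survival(net_do, treatment, as.character(code), outcome,
                            evidence = evidence, state = state), 0)
  ord <- order(-probs, candidates)
  top <- candidates[ord[1L]]
  tie <- sum(probs >= probs[ord[1L]] - 1e-12) > 1L
  structure(list(ranking = data.frame(code = candidates[ord],
                                      probability = probs[ord]),
                 top = top, tie = tie, evidence = evidence),
            class = "bn_recommendation")
}

#' @export
print.bn_recommendation <- function(x, ...) {
  cat(sprintf("<recommendation> top plan %d (P = %.3f)%s\n", x$top,
              x$ranking$probability[1L], if (x$tie) " [tie]" else ""))
  invisible(x)
}

#' Grouping of TNM categories into stage groups
#'
#' Early (IA-IIB), locally advanced (IIIA-IIIB), advanced (IV); the
#' `"Uncertain"` category forms its own stratum. Override to change the
#' grouping.
#'
#' @return Named character vector mapping TNM category to group.
#' @export
tnm_stage_groups <- function() {
  c(IA = "early", IB = "early", IIA = "early", IIB = "early",
    IIIA = "locally_advanced", IIIB = "locally_advanced",
    IV = "advanced", Uncertain = "uncertain")
}

#' Recorded-versus-recommended treatment concordance
#'
#' For every eligible patient the pre-treatment findings are entered as
#' evidence, the survival-maximising plan is obtained by causal intervention
#' on the treatment variable, and its concordance with the recorded plan is
#' classified as exact / partial / none. Aggregates a recorded-by-
#' recommended confusion matrix, overall exact and partial-or-exact rates,
#' and breakdowns per recorded plan and per TNM stage group.
#'
#' @param net A `bn_fit` trained *excluding* the cohort (re-parameterise via
#'   [mutilate()] with training data beforehand, or pass the plain net and
#'   the mutilation happens internally with the net's own marginal).
#' @param cohort Eligible records from [select_eligible()]; must be fully
#'   observed.
#' @param treatment,outcome Variable names.
#' @param candidates Candidate plan codes offered to the recommender.
#' @param tnm Name of the TNM category variable (`NULL` skips the stage
#'   breakdown).
#' @param stage_groups Mapping as from [tnm_stage_groups()].
#' @param state Outcome state being maximised.
#' @return An object of class `bn_concordance_report`.
#' @export
concordance <- function(net, cohort, treatment, outcome,
                        candidates = curative_codes(),
                        tnm = "TNMCategory",
                        stage_groups = tnm_stage_groups(),
                        state = "Alive") {
  if (any(cohort$mask == 0L))
    stop_usage("cohort contains missing cells; run select_eligible() first")
  nm <- var_names(cohort)
  pre_vars <- nm[tiers_of(cohort) == "pre_treatment"]
  candidates <- sort(as.integer(candidates))
  net_do <- mutilate(net, treatment)
  tstates <- net_do$variables[[treatment]]$states
  ostates <- net_do$variables[[outcome]]$states
  n <- nrow(cohort$x)
  # vectorised recommendation: clamp each candidate in turn and read the
  # posterior of the outcome given all pre-treatment variables + do(T)
  probs <- matrix(NA_real_, n, length(candidates),
                  dimnames = list(NULL, candidates))
  work <- cohort
  for (ci in seq_along(candidates)) {
    tidx <- match(as.character(candidates[ci]), tstates)
    if (is.na(tidx))
      stop_usage("candidate code ", candidates[ci],
                 " is not a state of '", treatment, "'")
    work$x[, treatment] <- tidx
    probs[, ci] <- predict_posterior(net_do, work, outcome)[, match(state, ostates)]
  }
  best_col <- max.col(probs, ties.method = "first")  # candidates sorted by code
  recommended <- candidates[best_col]
  ties <- vapply(seq_len(n), function(i)
    sum(probs[i, ] >= probs[i, best_col[i]] - 1e-12) > 1L, TRUE)
  recorded <- suppressWarnings(
    as.integer(tstates[cohort$x[, treatment]]))
  if (anyNA(recorded))
    stop_usage("cohort contains non-numeric treatment states; filter to curative plans")
  all_codes <- curative_codes()
  confusion <- table(factor(recorded, levels = all_codes),
                     factor(recommended, levels = all_codes))
  names(dimnames(confusion)) <- c("recorded", "recommended")
  levels_vec <- vapply(seq_len(n), function(i)
    match_level(recorded[i], recommended[i]), "")
  exact_rate <- mean(levels_vec == "exact")
  partial_or_exact_rate <- mean(levels_vec %in% c("exact", "partial"))
  per_treatment <- do.call(rbind, lapply(sort(unique(recorded)), function(code) {
    sel <- recorded == code
    data.frame(recorded = code, n = sum(sel),
               exact = mean(levels_vec[sel] == "exact"),
               partial_or_exact = mean(levels_vec[sel] %in% c("exact", "partial")))
  }))
  per_stage <- NULL
  if (!is.null(tnm) && tnm %in% nm) {
    tnm_states <- cohort$variables[[tnm]]$states
    grp <- stage_groups[tnm_states[cohort$x[, tnm]]]
    per_stage <- do.call(rbind, lapply(unique(grp[!is.na(grp)]), function(g) {
      sel <- !is.na(grp) & grp == g
      data.frame(stage_group = g, n = sum(sel),
                 exact = mean(levels_vec[sel] == "exact"),
                 partial_or_exact = mean(levels_vec[sel] %in% c("exact", "partial")))
    }))
  }
  structure(list(confusion = confusion, exact_rate = exact_rate,
                 partial_or_exact_rate = partial_or_exact_rate,
                 per_treatment = per_treatment, per_stage = per_stage,
                 n = n, ties = sum(ties), candidates = candidates,
                 interventional_probabilities = probs,
                 recommended = recommended, recorded = recorded,
                 match_levels = levels_vec),
            class = "bn_concordance_report")
}

#' @export
print.bn_concordance_report <- function(x, ...) {
  cat(sprintf("<bn_concordance_report> %d patients, %d candidate plans\n",
              x$n, length(x$candidates)))
  cat(sprintf("  exact concordance:            %.1f%%\n", 100 * x$exact_rate))
  cat(sprintf("  exact or partial concordance: %.1f%%\n",
              100 * x$partial_or_exact_rate))
  if (x$ties) cat(sprintf("  (%d recommendations were ties, broken by lowest code)\n",
                          x$ties))
  invisible(x)
}

#' Joint probability of surviving and receiving a treatment
#'
#' Multiplies the conditional survival probability given a treatment by the
#' marginal probability of that treatment being given; used to contrast the
#' conditional and joint views of treatment benefit.
#'
#' @param p_survival_given_treatment,p_treatment Probabilities in \[0, 1\].
#' @return Their product.
#' @export
joint_from_conditional <- function(p_survival_given_treatment, p_treatment) {
  for (p in c(p_survival_given_treatment, p_treatment)) {
    if (!is.numeric(p) || is.na(p) || p < 0 || p > 1)
      stop_usage("probabilities must lie in [0, 1]")
  }
  p_survival_given_treatment * p_treatment
}
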