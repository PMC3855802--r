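---
title: "Bayesian networks for lung cancer survival prediction and treatment recommendation"
author: "lungbn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian networks for lung cancer survival prediction and treatment recommendation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungbn)
```

## The problem

Treatment selection in lung cancer care happens under pervasive
uncertainty: a multidisciplinary team weighs a patient's age, lung
function, performance status, comorbidities, histology and stage against a
menu of treatment plans whose survival consequences are uncertain. Two
probabilistic questions capture the decision support need:

* **Prognosis** — `P(Survival = Alive | Evidence)`: an observational query,
  answerable by conditioning a joint distribution on what has been
  recorded.
* **Treatment choice** — `P(Survival = Alive | Evidence, do(T = t))`: a
  *causal* query about a treatment that has not yet been given. Answering
  it requires an intervention, not conditioning: regression-style
  discriminative models cannot express it.

A discrete Bayesian network (BN) supports both. It factorises the joint
distribution of the 13 clinical variables this package models (eleven
pre-treatment characteristics, the suggested treatment plan, and 1-year
survival) as `P(X) = prod_i P(X_i | pa(X_i))` over a directed acyclic
graph, with one conditional probability table (CPT) per variable.

`lungbn` implements the full analysis pipeline around that object:
pre-processing with explicit missingness, structure learning by manual,
automated and knowledge-constrained methods, Bayesian scoring, exact
inference, do-operator interventions, cross-validated evaluation, and a
recorded-versus-recommended treatment concordance analysis. Because the
national audit registry this style of analysis was developed on is not
publicly deposited, the package ships a first-class synthetic cohort
generator that reproduces the registry's published marginal facts, so
every stage of the pipeline is testable end to end.

## Explicit missingness instead of imputation

Clinical audit data is incomplete in an informative way: which fields are
filled in depends on how sick the patient is. Treating such data as
missing-at-random and imputing (EM, multiple imputation) yields biased
estimates. The package instead appends an explicit `"Unknown/Missing"`
state to any variable containing nulls (`encode_missing()`), making
missingness an ordinary category in counting, scoring and inference. The
observedness mask is retained, and `indicator_matrix()` +
`missingness_experiment()` quantify how predictive the missingness pattern
alone is of 1-year survival: under the generator's default
not-missing-at-random (NMAR) mechanism both a naive Bayes and a ridge
logistic baseline clearly beat chance on the indicators alone, and under a
missing-completely-at-random control they sit at AUC 0.5.

## Parameterisation and the structure score

CPTs are estimated by `fit_parameters()` as posterior means under a
uniform Dirichlet prior: `(N_ijk + a) / (N_ij + r_i a)` with pseudocount
`a = 1` per cell by default (the prior's equivalent sample size is not
something the underlying study pins down, so it is exposed as an
argument).

Structures are compared by the K2 (Cooper–Herskovits) Bayesian score, the
closed-form log marginal likelihood

```
log P(G, D) = log P(G) + sum_i sum_j [ log G(r_i) - log G(N_ij + r_i)
                                       + sum_k log G(N_ijk + 1) ]
```

(`G` = gamma function) implemented in log space throughout; a separate
exact-factorial oracle exists only in the test suite, because factorials
overflow double precision long before registry scale (n ~ 10^5). The score
is decomposable over node families, which the search algorithms exploit by
re-scoring only the families a move touches (with memoisation). The
structure prior `P(G)` defaults to uniform; the constrained search
supplies a non-uniform one (below).

One caution the test suite encodes: the K2 metric with per-cell
pseudocount 1 is *not* score-equivalent across edge reversals in general
(unlike BDeu), so "equivalent" structures can score slightly differently;
only genuinely exchangeable data makes the two directions of a
two-variable model score identically.

## Structure learning

Six learners cover the manual-to-automated spectrum:

* **Fixed/manual structures** are passed directly to `cross_validate()`.
* **`learn_tan()`** — tree-augmented naive Bayes: the class points at every
  predictor, and predictors form a maximum spanning tree on conditional
  mutual information `I(X_i; X_j | class)`.
* **`k2_search()`** — greedy parent selection under a user-supplied
  temporal/causal node ordering.
* **`anneal_search()`** — add/delete/reverse moves accepted by the
  Metropolis criterion with geometric cooling (default 200 sweeps, cooling
  0.99, initial temperature set from the median uphill move so about half
  of uphill moves are accepted at the start); best-seen structure
  returned, so the output never scores below the empty start state.
* **`mcmc_search()`** — the same move kernel at unit temperature; the
  highest-posterior visited DAG is returned and post-burn-in edge
  frequencies are attached. The proposal is not corrected for
  neighbourhood size, which matters for posterior sampling but not for the
  best-visited-structure use here.
* **`constraint_learn()`** — PC/IC-style: G² conditional-independence
  tests with growing conditioning sets prune a skeleton, v-structures and
  Meek rules orient it, and leftover edges are oriented by temporal tier
  then lexicographically (a deterministic, acyclicity-preserving
  tie-break). Tests whose degrees of freedom the sample cannot support are
  skipped with a warning and the edge kept.

### Expert knowledge as a prior

`structure_prior()` encodes two kinds of clinician knowledge: temporal
tiers (pre-treatment before treatment before outcome; an edge pointing
backwards in time is a violation) and pairwise relations — `A` precedes
`B`, `A` is related to `B`, `A` directly influences `B` — each with a
confidence weight. Confidence 1 makes a constraint hard: the search never
visits a violating structure. Confidence `c < 1` contributes prior
log-odds `log(c / (1 - c))` when the constraint is satisfied, so the
search maximises `log P(D | G) + log P(G)` and an expert hunch can be
overruled by enough data. The hybrid algorithm the underlying study used
(an MML-metric learner) is deliberately not reimplemented: its role —
expert priors inside automated search — is filled by this Bayesian-score
search, which is what the package's comparative claims exercise.

### Aggregating fold structures

Cross-validation produces one DAG per fold. `aggregate_dags()` weights
each directed edge by its fold frequency and extracts a maximum-weight
directed spanning structure (a maximum branching via Chu–Liu/Edmonds:
every node keeps at most one parent, cycles are contracted recursively),
so the aggregate is guaranteed acyclic, forests are handled, and unanimous
trees are recovered exactly. Fold frequency is used as the weight because
the procedure the study describes specifies none; score-weighted variants
were considered and rejected for simplicity.

## Inference and intervention

`posterior()` performs exact sum-product variable elimination with a
greedy smallest-factor ordering. With 13 variables of arity at most 13
this is comfortably exact; the contract is exactness (pinned against
full-joint enumeration oracles to 1e-10 in the tests), not a particular
message-passing mechanism such as a junction tree. Evidence with zero
probability raises an error rather than returning NaN, surfacing
data/state mismatches early. `predict_posterior()` is the vectorised
complete-evidence fast path (the Markov-blanket closed form) used by
cross-validation and the concordance analysis.

`mutilate()` implements the do-operator's graph surgery: all edges into
the intervened treatment variable are removed and its CPT replaced by a
parent-free marginal — computed exactly from the network itself, or
re-learned from a training dataset when the recommender is
re-parameterised away from a held-out cohort. Clamping the treatment as
evidence on the mutilated network then yields
`interventional_survival()`; for a parentless target this provably
coincides with ordinary conditioning, and mutilation is idempotent.

## Evaluation harness

`cross_validate()` mirrors the study design: stratified folds (default
`k = 10`) with near-equal outcome prevalence, structure + parameters
learned per fold, held-out records scored by the posterior of survival
given *all* other recorded variables — including the sentinel state as
genuine evidence, and including the treatment variable by default (it is
recorded before the outcome; an `exclude` argument drops it). AUC is the
Mann–Whitney probability that a positive outranks a negative with ties
counted one half; accuracy uses a fixed 0.5 posterior threshold (the
study does not state one). Baselines: naive Bayes (identical to the
star-structured BN posterior, which the tests verify to 1e-12) and a
ridge-penalised logistic regression fitted by Newton iterations to
gradient norm below 1e-6 with an unpenalised intercept.

## The synthetic registry

`build_truth_net()` constructs a 13-variable ground-truth network whose
shape follows the tier-respecting structures hybrid learners produce on
this domain: dependencies among pre-treatment variables, stage and
performance status as clinical-eligibility parents of the treatment
decision, and treatment plus stage, performance status and age as parents
of survival. Three published facts about the registry are treated as
calibration targets and verified by exact marginalisation at build time:

* 1-year survival prior 0.33 (within 0.005; the survival CPT's intercept
  is solved with `uniroot` against the exact parent joint);
* the treatment-plan frequency table, including a 14% unrecorded "Null"
  mass (each code within 0.01; iterative proportional column scaling with
  row renormalisation, at most 500 iterations);
* 32% overall missingness with an NMAR mechanism (within 0.01 of target):
  each pre-treatment cell is deleted with probability logistic in the
  record's severity proxy (0.6 x TNM severity + 0.4 x performance-status
  severity), slope `nmar_strength = 3`, intercept solved so the expected
  deletion rate hits the target. Strength 0 degrades gracefully to MCAR
  at the same rate. Severity is taken from the *pre-deletion* values, so
  the mechanism is genuinely not-missing-at-random; the default slope is
  chosen so the missingness pattern is clearly informative of survival
  (indicator AUC above 0.6 at registry-like scale), the qualitative
  phenomenon the missingness experiment exists to detect.

Everything else — the dependence strengths, the small log-scale jitter
(sd 0.15) that keeps tables generic, treatment lifts that favour surgical
plans — is a documented default, not an estimate: the registry publishes
no joint statistics. Two design choices are deliberate. Treatment
assignment in the generator follows *eligibility* (early stage and good
performance status make surgery likely), not survival maximisation; and
surgical plans carry the largest survival lift. Together these reproduce
the qualitative signature of the concordance analysis: a
survival-maximising recommender disagrees with most recorded plans
exactly, while agreeing far more often at the shared-modality (partial)
level, and its recommendations concentrate on surgical codes.

What passing tests on this cohort do **not** show: agreement with any real
registry's joint distribution, the published AUC/score table, or the
published 29%/76% concordance rates, all of which depend on data that is
not deposited. The package's claims on real-world-scale numbers are
ordering claims (e.g. a ground-truth structure beats a degraded "manual"
structure on both AUC and score; exact concordance is well below
partial-or-exact), verified on the synthetic cohort.

## Numerical and procedural choices

* Discretisation intervals are left-closed/right-open (`[50, 60)` is
  "50-60"); the published interval labels carry no boundary convention, so
  one was fixed and tested.
* Argmax ties in treatment recommendation are flagged and broken towards
  the lowest treatment code; lexicographic tie-breaks are used in search
  and aggregation, so every output is deterministic given its seed.
* Partial concordance is formalised as non-empty intersection of modality
  sets (surgery / chemotherapy / radiotherapy / palliative / monitoring);
  the motivating example — recorded "Surgery", recommended "Surgery
  followed by adjuvant chemotherapy" — is one instance of the rule, and
  the full curative-by-curative match table is exercised in the tests.
* TNM stage groups: early IA–IIB, locally advanced IIIA–IIIB, advanced
  IV, with "Uncertain" as its own stratum (the grouping is an argument).
* `max_parents` defaults to 4, bounding CPT row counts with arities up to
  13 states.
* Parameter-recovery expectations are statistical: a 2,200-row survival
  table at n = 20,000 leaves a Dirichlet(1) fit about 0.02 of AUC short of
  the generator's Bayes optimum, and rarely-visited parent configurations
  stay near the prior; the tests use binomial error bands rather than
  pretending estimation error away.

Problem sizes used by the test suite and acceptance script — cohorts of
20,000 (100,000 for marginal checks), 10-fold cross-validation, 100-net
inference oracles, 100 seeded constrained-search runs — were chosen to
make the statistical assertions sharp at desk scale.

## A worked run

```{r example, eval = FALSE}
cfg <- generator_config()
net <- build_truth_net(cfg)                    # calibrated ground truth
cohort <- apply_nmar(sample_cohort(net, 20000, seed = 1), cfg, seed = 2)

# survival prediction with the true structure vs a degraded manual one
cv <- cross_validate(cohort, default_truth_dag(), "Survival",
                     k = 10, seed = 3, positive = "Alive")
cv

# survival-maximising recommendation for the eligible cohort
eligible <- select_eligible(cohort, treatment = "Treatment")
ok <- rowSums(cohort$mask == 0L) == 0L &
  cohort$x[, "Treatment"] %in%
    match(as.character(curative_codes()), cohort$variables$Treatment$states)
train <- fit_parameters(default_truth_dag(),
                        bn_dataset(cohort$variables, cohort$x[!ok, ],
                                   cohort$mask[!ok, ]))
concordance(mutilate(train, "Treatment"), eligible, "Treatment", "Survival")
```

## Limitations

The recommender maximises 1-year survival and nothing else: suitability
for surgery, quality of life and cost are not modelled (the corresponding
variables do not exist in the variable set), which is precisely why a
survival-maximising argmax over-recommends surgery. Non-curative plans
are excluded from intervention by design. Inference is exact but assumes
the 13-variable discrete domain; continuous conditional distributions and
approximate inference are out of scope, as are utility-based decision
networks and 5-year outcomes.
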