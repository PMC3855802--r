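# Treatment plans, eligibility, recommendation and concordance.

test_that("the plan catalogue encodes curative status and modalities", {
  plans <- treatment_plans()
  expect_setequal(plans$code, c(1, 2, 3, 5, 6, 7, 8, 9, 10, 11))
  expect_setequal(plans$code[!plans$curative], c(5, 6))
  expect_setequal(surgical_codes(), c(1, 9, 10, 11))
  for (code in surgical_codes())
    expect_true("surgery" %in% plans$modalities[[match(code, plans$code)]])
  for (code in c(2, 3, 7, 8))
    expect_false("surgery" %in% plans$modalities[[match(code, plans$code)]])
})

test_that("match_level distinguishes exact, partial and no concordance", {
  expect_identical(match_level(1, 11), "partial")  # both involve surgery
  expect_identical(match_level(2, 2), "exact")
  expect_identical(match_level(2, 3), "none")      # radio vs chemo
  # full curative-by-curative table against modality-set intersection
  plans <- treatment_plans()
  cur <- curative_codes()
  for (a in cur) for (b in cur) {
    ma <- plans$modalities[[match(a, plans$code)]]
    mb <- plans$modalities[[match(b, plans$code)]]
    want <- if (a == b) "exact" else
      if (length(intersect(ma, mb))) "partial" else "none"
    expect_identical(match_level(a, b), want)
  }
  expect_error(match_level(4, 1), "unknown treatment code")
})

eligible_fixture <- function() {
  vars <- list(variable_spec("Diag", c("NSCLC", "SCLC", "Other")),
               variable_spec("X", c("lo", "hi")),
               variable_spec("Treatment", c("1", "2", "5", "Null"),
                             tier = "treatment"),
               variable_spec("Survival", c("Alive", "Dead"),
                             tier = "post_treatment"))
  vars[[2]] <- add_missing_state(vars[[2]])
  # 20 rows: 5 bad diagnosis, 5 non-curative treatment, 5 with a missing
  # cell, 5 clean - all disjoint
  diag <- c(rep(3L, 5), rep(1L, 15))
  treat <- c(rep(1L, 5), rep(3L, 3), rep(4L, 2), rep(1L, 10))
  xcol <- c(rep(1L, 10), rep(3L, 5), rep(2L, 5))
  mask <- matrix(1L, 20, 4)
  mask[11:15, 2] <- 0L
  d <- bn_dataset(vars, cbind(Diag = diag, X = xcol, Treatment = treat,
                              Survival = rep(1L, 20)), mask)
  d
}

test_that("eligibility keeps exactly the clean curative lung-cancer records", {
  d <- eligible_fixture()
  out <- select_eligible(d, treatment = "Treatment", diagnosis = "Diag",
                         diagnosis_states = c("NSCLC", "SCLC"),
                         curative = c("1", "2"))
  expect_equal(nrow(out$x), 5L)
  log <- attr(out, "selection_log")
  expect_equal(log$removed, c(5L, 5L, 5L))
  # a single sentinel cell excludes the record
  expect_true(all(out$mask == 1L))
  # identity on a fully clean curative cohort
  clean <- lungbn:::dataset_rows(d, 16:20)
  out2 <- select_eligible(clean, treatment = "Treatment",
                          curative = c("1", "2"))
  expect_equal(out2$x, clean$x)
})

test_that("recommend ranks by interventional survival with deterministic ties", {
  vars <- list(variable_spec("Stage", c("early", "late")),
               variable_spec("Treatment", c("1", "2", "3"),
                             tier = "treatment"),
               variable_spec("Survival", c("Alive", "Dead"),
                             tier = "post_treatment"))
  names(vars) <- c("Stage", "Treatment", "Survival")
  net <- make_net(vars,
                  rbind(c("Stage", "Treatment"), c("Stage", "Survival"),
                        c("Treatment", "Survival")),
                  list(Stage = c(0.7, 0.3),
                       Treatment = rbind(c(0.6, 0.3, 0.1), c(0.1, 0.4, 0.5)),
                       # Survival rows over (Stage, Treatment), stage fastest
                       Survival = rbind(c(0.9, 0.1), c(0.5, 0.5),
                                        c(0.6, 0.4), c(0.3, 0.7),
                                        c(0.7, 0.3), c(0.2, 0.8))))
  rec <- recommend(net, evidence = list(Stage = "early"),
                   treatment = "Treatment", outcome = "Survival",
                   candidates = c(1, 2, 3))
  # exhaustive check: with Stage observed, P(Alive | do(T)) is the CPT entry
  expect_equal(rec$ranking$code, c(1L, 3L, 2L))
  expect_equal(rec$ranking$probability, c(0.9, 0.7, 0.6))
  expect_equal(rec$top, 1L)
  expect_false(rec$tie)
  # single candidate: trivially top
  rec1 <- recommend(net, list(Stage = "late"), "Treatment", "Survival",
                    candidates = 2)
  expect_equal(rec1$top, 2L)
  # d-separated treatment: all equal, tie flagged, lowest code wins
  net2 <- make_net(vars, rbind(c("Stage", "Survival")),
                   list(Stage = c(0.7, 0.3),
                        Treatment = c(1 / 3, 1 / 3, 1 / 3),
                        Survival = rbind(c(0.8, 0.2), c(0.4, 0.6))))
  rec2 <- recommend(net2, list(Stage = "early"), "Treatment", "Survival",
                    candidates = c(2, 3))
  expect_true(rec2$tie)
  expect_equal(rec2$top, 2L)
})

concordance_fixture <- function() {
  # ten patients; hand-enumerable recommendations
  vars <- list(variable_spec("Stage", c("IA", "IV")),
               variable_spec("Treatment", as.character(c(1:3, 5:11)),
                             tier = "treatment"),
               variable_spec("Survival", c("Alive", "Dead"),
                             tier = "post_treatment"))
  names(vars) <- c("Stage", "Treatment", "Survival")
  # survival rows over (Stage, Treatment), stage fastest; surgery (code 1,
  # column 1) dominates for early stage, chemo-radio (7) for late stage
  p_alive <- rbind(
    early = c(0.9, 0.5, 0.5, 0.2, 0.3, 0.6, 0.6, 0.85, 0.85, 0.88),
    late  = c(0.3, 0.35, 0.4, 0.1, 0.15, 0.55, 0.5, 0.32, 0.33, 0.34))
  surv <- matrix(0, 20, 2)
  for (t in 1:10) {
    surv[2 * t - 1, ] <- c(p_alive["early", t], 1 - p_alive["early", t])
    surv[2 * t, ] <- c(p_alive["late", t], 1 - p_alive["late", t])
  }
  net <- make_net(vars,
                  rbind(c("Stage", "Treatment"), c("Stage", "Survival"),
                        c("Treatment", "Survival")),
                  list(Stage = c(0.5, 0.5),
                       Treatment = rbind(rep(0.1, 10), rep(0.1, 10)),
                       Survival = surv))
  list(net = net, vars = vars)
}

test_that("concordance matches a hand tally on a worked cohort", {
  fx <- concordance_fixture()
  codes <- as.character(c(1:3, 5:11))
  # five early patients treated with 1,2,3,7,11; five late with 2,3,7,8,11
  stage <- c(rep(1L, 5), rep(2L, 5))
  treat <- match(c("1", "2", "3", "7", "11", "2", "3", "7", "8", "11"), codes)
  cohort <- bn_dataset(fx$vars, cbind(Stage = stage, Treatment = treat,
                                      Survival = rep(1L, 10)))
  rep <- concordance(fx$net, cohort, "Treatment", "Survival", tnm = "Stage")
  # by hand: early-stage argmax over curative plans is plan 1 (0.9);
  # late-stage argmax is plan 7 (0.55)
  expect_true(all(rep$recommended[1:5] == 1L))
  expect_true(all(rep$recommended[6:10] == 7L))
  # exact matches: early patient treated with 1; late patient treated with 7
  expect_equal(rep$exact_rate, 2 / 10)
  # partials: early 11 (shares surgery with plan 1); late 2, 3, 8 and 11
  # (each shares chemo or radio with plan 7)
  expect_equal(rep$partial_or_exact_rate, 7 / 10)
  expect_equal(sum(rep$confusion), 10)
  expect_equal(unname(rep$confusion["2", "1"]), 1)
  # stage breakdown covers both strata
  expect_setequal(rep$per_stage$stage_group, c("early", "advanced"))
  # restricting the candidates zeroes the excluded columns
  rep2 <- concordance(fx$net, cohort, "Treatment", "Survival",
                      candidates = c(2, 3, 7, 8), tnm = "Stage")
  expect_true(all(rep2$confusion[, as.character(surgical_codes())] == 0))
  expect_true(all(rep2$recommended %in% c(2, 3, 7, 8)))
})

test_that("a generator whose recorded treatment is optimal gives perfect concordance", {
  fx <- concordance_fixture()
  codes <- as.character(c(1:3, 5:11))
  cohort <- bn_dataset(fx$vars, cbind(
    Stage = c(1L, 1L, 2L, 2L),
    Treatment = match(c("1", "1", "7", "7"), codes),
    Survival = rep(1L, 4)))
  rep <- concordance(fx$net, cohort, "Treatment", "Survival", tnm = "Stage")
  expect_equal(rep$exact_rate, 1)
  expect_lte(rep$exact_rate, rep$partial_or_exact_rate)
})

test_that("joint_from_conditional multiplies and validates", {
  expect_equal(signif(joint_from_conditional(0.81, 0.02), 2), 0.016)
  expect_equal(joint_from_conditional(0.37, 1), 0.37)
  expect_equal(joint_from_conditional(0, 0.9), 0)
  expect_error(joint_from_conditional(1.2, 0.5), "0, 1")
  expect_error(joint_from_conditional(0.5, -0.1), "0, 1")
})
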