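# Guideline-based MetS labeling: individual conditions, the three-of-five
# rule, and agreement with an independently hand-coded rule table.

test_that("individual diagnostic conditions apply inclusive thresholds", {
  crit <- mets_criteria()
  expect_true(evaluate_condition(healthy_record(WC = 92),
                                 "abdominal_obesity", crit))
  expect_true(evaluate_condition(healthy_record(sex = "female", WC = 85),
                                 "abdominal_obesity", crit))
  expect_false(evaluate_condition(healthy_record(WC = 89.9),
                                  "abdominal_obesity", crit))
  expect_false(evaluate_condition(healthy_record(TG = 1.69), "high_tg",
                                  crit))
  expect_true(evaluate_condition(healthy_record(TG = 1.70), "high_tg",
                                 crit))
  expect_true(evaluate_condition(healthy_record(HDLC = 1.04), "low_hdlc",
                                 crit))
  expect_false(evaluate_condition(healthy_record(HDLC = 1.05), "low_hdlc",
                                  crit))
  # blood pressure: either branch of the disjunction suffices
  expect_true(evaluate_condition(healthy_record(SBP = 130, DBP = 70),
                                 "hypertension", crit))
  expect_true(evaluate_condition(healthy_record(SBP = 118, DBP = 85),
                                 "hypertension", crit))
  expect_false(evaluate_condition(healthy_record(SBP = 129, DBP = 84),
                                  "hypertension", crit))
})

test_that("history flags and the configurable blood-pressure rule", {
  crit <- mets_criteria()
  expect_true(evaluate_condition(
    healthy_record(FGLU = 5.0, diabetes_history = TRUE), "hyperglycemia",
    crit))
  expect_true(evaluate_condition(
    healthy_record(hypertension_history = TRUE), "hypertension", crit))
  no_hist <- mets_criteria(history_satisfies = FALSE)
  expect_false(evaluate_condition(
    healthy_record(FGLU = 5.0, diabetes_history = TRUE), "hyperglycemia",
    no_hist))
  # literal conjunctive reading: measurement alone no longer suffices
  strict <- mets_criteria(bp_rule = "measured_and_history")
  expect_false(evaluate_condition(healthy_record(SBP = 150),
                                  "hypertension", strict))
  expect_true(evaluate_condition(
    healthy_record(SBP = 150, hypertension_history = TRUE),
    "hypertension", strict))
})

test_that("condition evaluation reports missing indicators and bad input", {
  expect_error(evaluate_condition(list(sex = "male", TG = NA_real_),
                                  "high_tg"), "TG")
  expect_error(evaluate_condition(list(sex = "male"), "abdominal_obesity"),
               "WC")
  expect_error(evaluate_condition(healthy_record(), "nonsense"),
               "unknown condition")
  expect_error(mets_criteria(min_conditions = 6), "min_conditions")
  expect_error(mets_criteria(tg = -1), "positive")
})

test_that("three-of-five rule counts and labels correctly", {
  d <- diagnose_mets(healthy_record(WC = 92, FGLU = 6.5, TG = 1.9,
                                    HDLC = 1.20, SBP = 120, DBP = 80))
  expect_equal(d$n_conditions_met, 3)
  expect_equal(d$label, 1L)
  d2 <- diagnose_mets(healthy_record(WC = 92, TG = 1.9))
  expect_equal(d2$n_conditions_met, 2)
  expect_equal(d2$label, 0L)
  d5 <- diagnose_mets(healthy_record(WC = 95, FGLU = 7, TG = 2.5,
                                     HDLC = 0.9, SBP = 140))
  expect_equal(d5$n_conditions_met, 5)
  expect_equal(d5$label, 1L)
})

test_that("diagnosis agrees with a hand-coded rule table on the 3^5 boundary grid", {
  # Independent truth: literal arithmetic on the printed thresholds.
  wc_v <- c(89.9, 90, 90.1)
  fglu_v <- c(6.0, 6.1, 6.2)
  sbp_v <- c(129, 130, 131)
  tg_v <- c(1.69, 1.70, 1.71)
  hdlc_v <- c(1.05, 1.04, 1.03)
  grid <- expand.grid(wc = wc_v, fglu = fglu_v, sbp = sbp_v, tg = tg_v,
                      hdlc = hdlc_v)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    truth_n <- (g$wc >= 90) + (g$fglu >= 6.1) + (g$sbp >= 130) +
      (g$tg >= 1.70) + (g$hdlc <= 1.04)
    d <- diagnose_mets(healthy_record(WC = g$wc, FGLU = g$fglu,
                                      SBP = g$sbp, DBP = 70, TG = g$tg,
                                      HDLC = g$hdlc))
    expect_equal(d$n_conditions_met, truth_n)
    expect_equal(d$label, as.integer(truth_n >= 3))
  }
})

test_that("diagnosis is monotone in risk direction", {
  set.seed(7)
  for (rep in 1:50) {
    rec <- healthy_record(WC = runif(1, 70, 100), FGLU = runif(1, 4, 7),
                          SBP = runif(1, 100, 150), DBP = runif(1, 60, 95),
                          TG = runif(1, 0.5, 2.5),
                          HDLC = runif(1, 0.8, 1.8))
    base_n <- diagnose_mets(rec)$n_conditions_met
    worse <- rec
    ind <- sample(c("WC", "FGLU", "SBP", "TG", "HDLC"), 1)
    if (ind == "HDLC") worse$HDLC <- worse$HDLC - runif(1, 0, 0.5)
    else worse[[ind]] <- worse[[ind]] + runif(1, 0, 20)
    expect_gte(diagnose_mets(worse)$n_conditions_met, base_n)
  }
})

test_that("vectorized diagnosis matches the record-wise path", {
  set.seed(11)
  df <- data.frame(sex = sample(c("male", "female"), 40, TRUE),
                   WC = runif(40, 70, 100), FGLU = runif(40, 4, 7.5),
                   SBP = runif(40, 100, 150), DBP = runif(40, 60, 95),
                   TG = runif(40, 0.5, 2.5), HDLC = runif(40, 0.8, 1.8))
  tab <- diagnose_mets_table(df)
  for (i in seq_len(nrow(df))) {
    d <- diagnose_mets(as.list(df[i, ]))
    expect_equal(tab$n_conditions[i], d$n_conditions_met)
    expect_equal(tab$ms_result[i], d$label)
  }
})

test_that("registry validation enforces its invariants", {
  reg <- default_indicator_registry()
  expect_s3_class(reg, "indicator_registry")
  expect_silent(validate_indicator_registry(reg))
  bad <- reg
  bad$risk_direction[bad$indicator == "TG"] <- "low_is_risk"
  expect_error(validate_indicator_registry(bad), "HDLC")
  bad2 <- reg
  bad2$scale_max[1] <- -1
  expect_error(validate_indicator_registry(bad2), "scale_max")
  bad3 <- reg
  bad3$upper_male[bad3$indicator == "TG"] <- NA
  bad3$lower_male[bad3$indicator == "TG"] <- NA
  expect_error(validate_indicator_registry(bad3), "limit")
  # sex-specific lookup: WC limit differs by sex, risk-direction aware
  expect_equal(metsflow:::indicator_limit(reg, "WC", "male"), 90)
  expect_equal(metsflow:::indicator_limit(reg, "WC", "female"), 85)
  expect_equal(metsflow:::indicator_limit(reg, "HDLC", "male"), 1.04)
})
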