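#' Names of the continuous clinical indicators handled by the pipeline
#'
#' The 18 continuous indicators tracked per person-year: waist circumference
#' (WC), waist-to-hip ratio (WHR), systolic/diastolic blood pressure
#' (SBP/DBP), triglycerides (TG), HDL cholesterol (HDLC), LDL cholesterol
#' (LDLC), body-mass index (BMI), total cholesterol (TC), fasting glucose
#' (FGLU), uric acid (UA), alanine/aspartate aminotransferase (ALT/AST),
#' hemoglobin (HGB), red/white blood cell counts (RBC/WBC), platelets (PLT)
#' and creatinine (CR).
#'
#' @return Character vector of indicator names.
#' @export
mets_indicators <- function() {
  c("WC", "WHR", "SBP", "DBP", "TG", "HDLC", "LDLC", "BMI", "TC", "FGLU",
    "UA", "ALT", "AST", "HGB", "RBC", "WBC", "PLT", "CR")
}

#' Indicators entering the MetS diagnostic rule
#'
#' The five-condition rule uses WC, FGLU, SBP, DBP, TG and HDLC. For these,
#' abnormality conventions reuse the printed inclusive diagnostic thresholds.
#'
#' @return Character vector.
#' @export
mets_core_indicators <- function() {
  c("WC", "FGLU", "SBP", "DBP", "TG", "HDLC")
}

#' Read an indicator registry from CSV
#'
#' The registry holds, per indicator: units, sex-specific normal-range limits
#' (lower/upper, either may be absent), the risk direction (`high_is_risk` or,
#' for HDL-C only, `low_is_risk`), physician plausibility bounds used for
#' outlier screening (distinct from the normal range), and `scale_max`, the
#' positive constant that normalizes the risk distance before the sigmoid
#' weight. `scale_max` may be left `NA` and frozen later from a training
#' cohort with [freeze_scale_max()].
#'
#' @param file Path to a CSV with columns `indicator, units, lower_male,
#'   upper_male, lower_female, upper_female, risk_direction, plaus_lower,
#'   plaus_upper, scale_max`.
#' @return A data.frame of class `indicator_registry`.
#' @export
read_indicator_registry <- function(file) {
  reg <- utils::read.csv(file, stringsAsFactors = FALSE)
  class(reg) <- c("indicator_registry", "data.frame")
  validate_indicator_registry(reg)
  reg
}

#' Default indicator registry shipped with the package
#'
#' Normal-range limits for the six MetS-rule indicators are the diagnostic
#' thresholds of the Chinese 2017 T2DM guideline; limits for the remaining
#' indicators are standard adult reference ranges (overridable — they are not
#' taken from any single study). Plausibility bounds are broad physiological
#' ranges used only to flag impossible measurements.
#'
#' @return An `indicator_registry` data.frame.
#' @export
default_indicator_registry <- function() {
  read_indicator_registry(
    system.file("extdata", "indicator_ranges.csv", package = "metsflow",
                mustWork = TRUE))
}

#' Validate an indicator registry
#'
#' Checks the structural invariants: required columns present, at least one
#' limit per indicator and sex, lower < upper where both exist,
#' `low_is_risk` only for HDLC, and positive `scale_max` where set.
#'
#' @param reg An `indicator_registry`.
#' @return The registry, invisibly; errors on violation.
#' @export
validate_indicator_registry <- function(reg) {
  needed <- c("indicator", "units", "lower_male", "upper_male",
              "lower_female", "upper_female", "risk_direction",
              "plaus_lower", "plaus_upper", "scale_max")
  missing_cols <- setdiff(needed, names(reg))
  if (length(missing_cols))
    stop("indicator registry lacks columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(reg$indicator))
    stop("duplicate indicator rows in registry")
  if (!all(reg$risk_direction %in% c("high_is_risk", "low_is_risk")))
    stop("risk_direction must be 'high_is_risk' or 'low_is_risk'")
  bad_low <- reg$indicator[reg$risk_direction == "low_is_risk" &
                             reg$indicator != "HDLC"]
  if (length(bad_low))
    stop("low_is_risk is reserved for deficit-type indicators (HDLC), got: ",
         paste(bad_low, collapse = ", "))
  for (side in c("male", "female")) {
    lo <- reg[[paste0("lower_", side)]]
    up <- reg[[paste0("upper_", side)]]
    if (any(is.na(lo) & is.na(up)))
      stop("every indicator needs at least one normal-range limit (",
           side, ")")
    both <- !is.na(lo) & !is.na(up)
    if (any(both & lo >= up))
      stop("lower limit must be below upper limit")
  }
  if (any(!is.na(reg$scale_max) & reg$scale_max <= 0))
    stop("scale_max must be positive")
  invisible(reg)
}

# Risk-direction limit for one indicator/sex: the upper limit when high
# values are risky, the lower limit for HDLC.
indicator_limit <- function(reg, indicator, sex) {
  i <- match(indicator, reg$indicator)
  if (is.na(i)) stop("unknown indicator: ", indicator)
  side <- if (identical(sex, "female")) "female" else "male"
  lim <- if (reg$risk_direction[i] == "high_is_risk")
    reg[[paste0("upper_", side)]][i] else reg[[paste0("lower_", side)]][i]
  if (is.na(lim))
    stop("indicator ", indicator, " has no ", reg$risk_direction[i],
         " limit for sex ", side)
  lim
}

# Vectorized over sex; returns per-record limit for one indicator.
indicator_limit_vec <- function(reg, indicator, sex) {
  i <- match(indicator, reg$indicator)
  if (is.na(i)) stop("unknown indicator: ", indicator)
  col <- if (reg$risk_direction[i] == "high_is_risk") "upper_" else "lower_"
  lim <- ifelse(sex == "female", reg[[paste0(col, "female")]][i],
                reg[[paste0(col, "male")]][i])
  if (anyNA(lim))
    stop("indicator ", indicator, " lacks a risk-direction limit")
  lim
}

#' MetS diagnostic criteria (Chinese 2017 T2DM guideline)
#'
#' A MetS diagnosis requires at least `min_conditions` (default 3) of five
#' conditions: abdominal obesity (WC >= 90 cm men / 85 cm women),
#' hyperglycemia (fasting glucose >= 6.1 mmol/L, or 2-h postprandial glucose
#' >= 7.8 mmol/L when measured, or diagnosed diabetes), elevated blood
#' pressure (SBP >= 130 or DBP >= 85 mmHg, or diagnosed hypertension),
#' fasting TG >= 1.70 mmol/L, and fasting HDL-C <= 1.04 mmol/L. All
#' thresholds are inclusive as printed.
#'
#' @param wc_male,wc_female Waist-circumference thresholds (cm).
#' @param fglu Fasting-glucose threshold (mmol/L).
#' @param pg 2-h postprandial glucose threshold (mmol/L); used only when a
#'   `PG` column is present.
#' @param sbp,dbp Blood-pressure thresholds (mmHg).
#' @param tg Triglyceride threshold (mmol/L).
#' @param hdlc HDL-C threshold (mmol/L; at or below is abnormal).
#' @param min_conditions Number of conditions required for a diagnosis.
#' @param bp_rule `"measured_or_history"` (default): elevated measured BP or
#'   a diagnosed-hypertension flag satisfies the condition.
#'   `"measured_and_history"`: the literal conjunctive reading, requiring
#'   both; unusable on exam-only data and provided for comparison.
#' @param history_satisfies Should diagnosed-diabetes/-hypertension history
#'   flags (when present) satisfy the corresponding condition even if the
#'   measurement is normal? Default `TRUE`.
#' @return A list of class `mets_criteria`.
#' @export
mets_criteria <- function(wc_male = 90, wc_female = 85, fglu = 6.1, pg = 7.8,
                          sbp = 130, dbp = 85, tg = 1.70, hdlc = 1.04,
                          min_conditions = 3,
                          bp_rule = c("measured_or_history",
                                      "measured_and_history"),
                          history_satisfies = TRUE) {
  bp_rule <- match.arg(bp_rule)
  thr <- c(wc_male = wc_male, wc_female = wc_female, fglu = fglu, pg = pg,
           sbp = sbp, dbp = dbp, tg = tg, hdlc = hdlc)
  if (any(thr <= 0)) stop("all thresholds must be strictly positive")
  if (!(min_conditions %in% 1:5))
    stop("min_conditions must be in 1..5")
  structure(list(wc_male = wc_male, wc_female = wc_female, fglu = fglu,
                 pg = pg, sbp = sbp, dbp = dbp, tg = tg, hdlc = hdlc,
                 min_conditions = min_conditions, bp_rule = bp_rule,
                 history_satisfies = history_satisfies),
            class = "mets_criteria")
}

mets_condition_names <- function() {
  c("abdominal_obesity", "hyperglycemia", "hypertension", "high_tg",
    "low_hdlc")
}

# One column of the condition matrix, vectorized over records.
# df needs sex plus the indicator columns the condition uses; NA propagates.
.condition_vec <- function(df, condition, criteria) {
  get <- function(col) if (col %in% names(df)) df[[col]] else
    rep(NA_real_, nrow(df))
  flag <- function(col) if (col %in% names(df))
    !is.na(df[[col]]) & df[[col]] else rep(FALSE, nrow(df))
  switch(condition,
    abdominal_obesity = {
      thr <- ifelse(df$sex == "female", criteria$wc_female, criteria$wc_male)
      get("WC") >= thr
    },
    hyperglycemia = {
      meas <- get("FGLU") >= criteria$fglu
      if ("PG" %in% names(df)) {
        pg_ab <- !is.na(df$PG) & df$PG >= criteria$pg
        meas <- ifelse(is.na(meas), pg_ab, meas | pg_ab)
      }
      if (criteria$history_satisfies) meas | flag("diabetes_history")
      else meas
    },
    hypertension = {
      meas <- get("SBP") >= criteria$sbp | get("DBP") >= criteria$dbp
      hist <- flag("hypertension_history")
      if (criteria$bp_rule == "measured_and_history") meas & hist
      else if (criteria$history_satisfies) meas | hist
      else meas
    },
    high_tg = get("TG") >= criteria$tg,
    low_hdlc = get("HDLC") <= criteria$hdlc,
    stop("unknown condition: ", condition)
  )
}

#' Evaluate one MetS diagnostic condition on a single record
#'
#' @param record A named list or one-row data.frame with `sex`
#'   (`"male"`/`"female"`) and the indicator(s) the condition needs
#'   (`WC`, `FGLU`/`PG`, `SBP`/`DBP`, `TG`, `HDLC`), optionally
#'   `diabetes_history` / `hypertension_history` logical flags.
#' @param condition One of `"abdominal_obesity"`, `"hyperglycemia"`,
#'   `"hypertension"`, `"high_tg"`, `"low_hdlc"`.
#' @param criteria A [mets_criteria()] object.
#' @return Logical scalar.
#' @export
evaluate_condition <- function(record, condition,
                               criteria = mets_criteria()) {
  if (!condition %in% mets_condition_names())
    stop("unknown condition: ", condition)
  df <- as.data.frame(record[!vapply(record, is.null, logical(1))],
                      stringsAsFactors = FALSE)
  needed <- switch(condition,
    abdominal_obesity = "WC",
    hyperglycemia = "FGLU",
    hypertension = c("SBP", "DBP"),
    high_tg = "TG",
    low_hdlc = "HDLC")
  if (is.null(df$sex)) stop("record is missing 'sex'")
  for (col in needed) {
    if (is.null(df[[col]]) || is.na(df[[col]]))
      stop("missing required indicator for ", condition, ": ", col)
  }
  out <- .condition_vec(df, condition, criteria)
  isTRUE(out[1])
}

#' Diagnose metabolic syndrome on a single record
#'
#' Applies the five-condition rule; a label of 1 means at least
#' `criteria$min_conditions` conditions are met.
#'
#' @inheritParams evaluate_condition
#' @return List with `label` (0/1) and `n_conditions_met`.
#' @export
diagnose_mets <- function(record, criteria = mets_criteria()) {
  met <- vapply(mets_condition_names(), function(cond)
    evaluate_condition(record, cond, criteria), logical(1))
  n <- sum(met)
  list(label = as.integer(n >= criteria$min_conditions),
       n_conditions_met = n)
}

#' Diagnose metabolic syndrome on a table of records
#'
#' Vectorized five-condition diagnosis. Records with any required indicator
#' missing get `NA` in both output columns (they cannot be labeled).
#'
#' @param df Data.frame with `sex` and indicator columns (`WC`, `FGLU`,
#'   `SBP`, `DBP`, `TG`, `HDLC`, optionally `PG` and history flags).
#' @param criteria A [mets_criteria()] object.
#' @return `df` with added integer columns `n_conditions` and `ms_result`.
#' @export
diagnose_mets_table <- function(df, criteria = mets_criteria()) {
  conds <- vapply(mets_condition_names(), function(cond)
    .condition_vec(df, cond, criteria), logical(nrow(df)))
  if (nrow(df) == 1L) conds <- matrix(conds, nrow = 1)
  n <- rowSums(conds)
  df$n_conditions <- as.integer(n)
  df$ms_result <- as.integer(n >= criteria$min_conditions)
  df
}
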