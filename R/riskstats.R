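#' Abnormal-state flag for an original indicator value
#'
#' A value is abnormal when it lies beyond the risk-direction normal limit:
#' above the upper limit for high-risk indicators, below the lower limit
#' for deficit-type indicators (HDL-C). The comparison is strict by
#' default ("exceeds the limit"); for the MetS diagnostic indicators the
#' printed inclusive thresholds are reused, so pass `inclusive = TRUE` for
#' those.
#'
#' @param value Numeric vector.
#' @param limit Risk-direction limit (scalar or same length).
#' @param risk_direction `"high_is_risk"` or `"low_is_risk"`.
#' @param inclusive Count the limit itself as abnormal.
#' @return Logical vector (`NA` where the value is missing).
#' @export
flag_abnormal_original <- function(value, limit,
                                   risk_direction = "high_is_risk",
                                   inclusive = FALSE) {
  if (any(is.na(limit))) stop("missing normal-range limit")
  if (risk_direction == "low_is_risk") {
    if (inclusive) value <= limit else value < limit
  } else {
    if (inclusive) value >= limit else value > limit
  }
}

#' Odds ratio with Woolf 95% confidence interval from a 2x2 table
#'
#' `OR = (a d) / (b c)` for the table exposed-cases `a`, exposed-noncases
#' `b`, unexposed-cases `c`, unexposed-noncases `d`. The interval is the
#' log-normal (Woolf) one, `exp(log OR +/- z * sqrt(1/a+1/b+1/c+1/d))`.
#' Zero cells get the Haldane-Anscombe 0.5 continuity correction (applied
#' to every cell, reported via `corrected`); with `correction = FALSE` a
#' table whose cross-product is undefined yields `NA` with a reason.
#'
#' @param a,b,c,d Cell counts; alternatively `a` may be a length-4 vector.
#' @param conf_level Confidence level (default 0.95).
#' @param correction Apply the 0.5 correction when any cell is zero.
#' @return List: `or, ci_low, ci_high, corrected, cells`, and `reason` when
#'   the estimate is undefined.
#' @export
odds_ratio <- function(a, b = NULL, c = NULL, d = NULL, conf_level = 0.95,
                       correction = TRUE) {
  if (is.null(b)) {
    stopifnot(length(a) == 4)
    cells <- as.numeric(a)
  } else cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  names(cells) <- c("a", "b", "c", "d")
  used <- cells
  corrected <- FALSE
  if (any(cells == 0)) {
    if (!correction) {
      or_raw <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
      return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  corrected = FALSE, cells = cells,
                  reason = if (is.nan(or_raw)) "undefined cross-product"
                           else "zero cell without correction"))
    }
    used <- cells + 0.5
    corrected <- TRUE
  }
  or <- unname((used["a"] * used["d"]) / (used["b"] * used["c"]))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / used))
  list(or = or,
       ci_low = unname(exp(log(or) - z * se)),
       ci_high = unname(exp(log(or) + z * se)),
       corrected = corrected, cells = cells)
}

# Exposure flags for the OR/prevalence analyses, from a feature matrix.
# Originals: most recent input year (y4), strict limits except the MetS
# diagnostic indicators (inclusive). DFFs: |g| above the cohort mean |g|.
.exposure_flags <- function(features, registry,
                            dff_by_sex = FALSE) {
  sex <- ifelse(features$sex_male == 1, "male", "female")
  inds <- registry$indicator[vapply(registry$indicator, function(i)
    sprintf("%s_y4", i) %in% names(features), logical(1))]
  flags <- list()
  for (ind in inds) {
    ri <- match(ind, registry$indicator)
    lim <- indicator_limit_vec(registry, ind, sex)
    flags[[ind]] <- flag_abnormal_original(
      features[[sprintf("%s_y4", ind)]], lim,
      registry$risk_direction[ri],
      inclusive = ind %in% mets_core_indicators())
  }
  for (ind in inds) {
    col <- sprintf("%s_DFF", ind)
    if (!col %in% names(features)) next
    g <- features[[col]]
    if (dff_by_sex) {
      fl <- logical(length(g))
      for (s in unique(sex)) fl[sex == s] <- flag_abnormal_dff(g[sex == s])
      flags[[col]] <- fl
    } else flags[[col]] <- flag_abnormal_dff(g)
  }
  flags
}

#' Stratified odds-ratio table by sex and age group
#'
#' For every feature (original indicators, exposure = abnormal value in the
#' most recent input year; and DFFs, exposure = absolute value above the
#' cohort mean) and every sex x age-group stratum, the 2x2 table against
#' the next-year MetS label and its odds ratio with 95% CI. Rows with an
#' empty stratum or an undefined estimate carry `NA`.
#'
#' @param features Feature matrix from [build_feature_matrix()] (needs the
#'   `{IND}_y4` and, for DFF rows, `{IND}_DFF` columns plus `age`,
#'   `sex_male`, `ms_result`).
#' @param registry An `indicator_registry`.
#' @param include_overall Also emit pooled rows (`sex = "all"`,
#'   `age_group = "all"`).
#' @param dff_by_sex Compute the DFF abnormality cut per sex instead of on
#'   the pooled cohort.
#' @param conf_level Confidence level for the Woolf interval.
#' @return Data.frame: `feature, type, sex, age_group, a, b, c, d, or,
#'   ci_low, ci_high, corrected`.
#' @export
stratified_or_table <- function(features,
                                registry = default_indicator_registry(),
                                include_overall = TRUE,
                                dff_by_sex = FALSE, conf_level = 0.95) {
  flags <- .exposure_flags(features, registry, dff_by_sex)
  sex <- ifelse(features$sex_male == 1, "male", "female")
  age_group <- as.character(assign_age_group(features$age))
  y <- features$ms_result
  sexes <- c("male", "female", if (include_overall) "all")
  groups <- c("18-44", "45-59", ">=60", if (include_overall) "all")
  rows <- list()
  for (feat in names(flags)) {
    fl <- flags[[feat]]
    type <- if (grepl("_DFF$", feat)) "DFF" else "original"
    for (s in sexes) {
      for (g in groups) {
        sel <- (s == "all" | sex == s) & (g == "all" | age_group == g)
        sel <- sel & !is.na(fl) & !is.na(y)
        if (!any(sel)) {
          rows[[length(rows) + 1]] <- data.frame(
            feature = feat, type = type, sex = s, age_group = g,
            a = NA, b = NA, c = NA, d = NA, or = NA_real_,
            ci_low = NA_real_, ci_high = NA_real_, corrected = NA,
            stringsAsFactors = FALSE)
          next
        }
        tab <- c(a = sum(fl[sel] & y[sel] == 1),
                 b = sum(fl[sel] & y[sel] == 0),
                 c = sum(!fl[sel] & y[sel] == 1),
                 d = sum(!fl[sel] & y[sel] == 0))
        est <- odds_ratio(tab, conf_level = conf_level)
        rows[[length(rows) + 1]] <- data.frame(
          feature = feat, type = type, sex = s, age_group = g,
          a = tab[["a"]], b = tab[["b"]], c = tab[["c"]], d = tab[["d"]],
          or = est$or, ci_low = est$ci_low, ci_high = est$ci_high,
          corrected = est$corrected, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Prevalence of MetS given an abnormal feature state
#'
#' `P(ms_result = 1 | flag)`, the conditional prevalence among samples
#' flagged abnormal.
#'
#' @param flag Logical exposure vector.
#' @param label 0/1 outcome vector.
#' @return Fraction, or `NA` when nothing is flagged.
#' @export
prevalence_given_state <- function(flag, label) {
  sel <- !is.na(flag) & flag
  if (!any(sel)) return(NA_real_)
  mean(label[sel] == 1)
}

#' Per-indicator MetS prevalence under abnormal DFF vs abnormal DNF
#'
#' For every indicator with both columns present: the prevalence of the
#' next-year MetS label among samples whose DFF is abnormal (absolute
#' value above the cohort mean) and among samples whose most recent
#' year-to-year difference (DNF, interval y3-y4) is abnormal (positive).
#'
#' @inheritParams stratified_or_table
#' @return Data.frame `indicator, prev_dff, n_dff, prev_dnf, n_dnf`.
#' @export
prevalence_table <- function(features,
                             registry = default_indicator_registry()) {
  y <- features$ms_result
  inds <- registry$indicator[vapply(registry$indicator, function(i)
    all(sprintf("%s_%s", i, c("DFF", "DNF3")) %in% names(features)),
    logical(1))]
  rows <- lapply(inds, function(ind) {
    dff_flag <- flag_abnormal_dff(features[[sprintf("%s_DFF", ind)]])
    dnf_flag <- flag_abnormal_dnf(features[[sprintf("%s_DNF3", ind)]])
    data.frame(indicator = ind,
               prev_dff = prevalence_given_state(dff_flag, y),
               n_dff = sum(dff_flag, na.rm = TRUE),
               prev_dnf = prevalence_given_state(dnf_flag, y),
               n_dnf = sum(dnf_flag, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
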