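#' Assign the WHO-style age group used for stratified analysis
#'
#' @param age Numeric vector of ages (years), all >= 18.
#' @return Factor with levels `"18-44"`, `"45-59"`, `">=60"`.
#' @export
assign_age_group <- function(age) {
  if (any(!is.na(age) & age < 18))
    stop("age below 18 is outside the study population")
  cut(age, breaks = c(18, 45, 60, Inf), right = FALSE,
      labels = c("18-44", "45-59", ">=60"))
}

#' Build 5-year prediction windows
#'
#' A window is four consecutive exam years in which the subject is MetS-free
#' plus the immediately following year, whose MetS diagnosis is the label
#' (`ms_result`). Windows containing a MetS-positive input year, gaps in the
#' year sequence, a label-year age under 18, or any missing diagnostic
#' indicator are not emitted. By default each subject contributes at most
#' their first eligible window; `per_subject = "all"` emits every eligible
#' (overlapping) window.
#'
#' @param cohort Cleaned cohort data.frame (one row per subject-year) with
#'   `subject_id, sex, age, year` and at least the diagnostic indicators
#'   `WC, FGLU, SBP, DBP, TG, HDLC`.
#' @param criteria A [mets_criteria()].
#' @param input_years Number of healthy input years (fixed design: 4).
#' @param per_subject `"first"` (default) or `"all"`.
#' @param indicators Indicator columns carried into the window table;
#'   default every registry indicator present in `cohort`.
#' @return List with `samples` — one row per window: `subject_id, sex,
#'   age_at_label, age_group, ms_result` and `{IND}_y1 .. {IND}_y4` value
#'   columns — and `counts` (`n_total`, `n_positive`, `n_negative`).
#' @export
build_windows <- function(cohort, criteria = mets_criteria(),
                          input_years = 4,
                          per_subject = c("first", "all"),
                          indicators = NULL) {
  per_subject <- match.arg(per_subject)
  stopifnot(input_years >= 1)
  if (is.null(indicators))
    indicators <- intersect(mets_indicators(), names(cohort))
  span <- input_years + 1

  df <- cohort[order(cohort$subject_id, cohort$year), , drop = FALSE]
  df <- diagnose_mets_table(df, criteria)
  n <- nrow(df)
  counts <- c(n_total = 0L, n_positive = 0L, n_negative = 0L)
  empty <- list(samples = data.frame(), counts = counts)
  if (n < span) return(empty)

  # A window starts at i if rows i..i+span-1 are the same subject with
  # consecutive years, labels 0 through i+span-2, and label-year fields set.
  ok <- rep(TRUE, n - span + 1)
  idx <- seq_len(n - span + 1)
  for (k in seq_len(span - 1)) {
    ok <- ok &
      df$subject_id[idx + k] == df$subject_id[idx] &
      df$year[idx + k] == df$year[idx] + k
  }
  for (k in seq_len(span - 1) - 1) {
    lab <- df$ms_result[idx + k]
    ok <- ok & !is.na(lab) & lab == 0
  }
  lab5 <- df$ms_result[idx + span - 1]
  age5 <- df$age[idx + span - 1]
  ok <- ok & !is.na(lab5) & !is.na(age5) & age5 >= 18

  starts <- idx[ok]
  if (per_subject == "first")
    starts <- starts[!duplicated(df$subject_id[starts])]
  if (!length(starts)) return(empty)

  samples <- data.frame(
    subject_id = df$subject_id[starts],
    sex = df$sex[starts],
    age_at_label = df$age[starts + span - 1],
    start_year = df$year[starts],
    ms_result = df$ms_result[starts + span - 1],
    stringsAsFactors = FALSE)
  samples$age_group <- assign_age_group(samples$age_at_label)
  for (ind in indicators) {
    for (k in seq_len(input_years)) {
      samples[[sprintf("%s_y%d", ind, k)]] <- df[[ind]][starts + k - 1]
    }
  }
  counts <- c(n_total = nrow(samples),
              n_positive = sum(samples$ms_result == 1L),
              n_negative = sum(samples$ms_result == 0L))
  list(samples = samples, counts = counts)
}
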