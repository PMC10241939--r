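#' Cleaning report
#'
#' Accumulates what the cleaning chain did: subject/record counts in and
#' out, features dropped (with reasons), per-indicator imputation counts and
#' the fill statistic used.
#'
#' @param n_subjects_in,n_records_in Input sizes.
#' @return A `cleaning_report` object; the chain functions update it.
#' @keywords internal
new_cleaning_report <- function(n_subjects_in = NA_integer_,
                                n_records_in = NA_integer_) {
  structure(list(n_subjects_in = n_subjects_in,
                 n_subjects_out = n_subjects_in,
                 n_records_in = n_records_in,
                 n_records_out = n_records_in,
                 dropped_features = data.frame(feature = character(),
                                               reason = character(),
                                               stringsAsFactors = FALSE),
                 outlier_cells = integer(),
                 imputed_counts = integer(),
                 imputation_method = character()),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report\n")
  cat(sprintf("  subjects: %s -> %s\n", x$n_subjects_in, x$n_subjects_out))
  cat(sprintf("  records:  %s -> %s\n", x$n_records_in, x$n_records_out))
  if (nrow(x$dropped_features)) {
    cat("  dropped features:\n")
    for (i in seq_len(nrow(x$dropped_features)))
      cat(sprintf("    %s (%s)\n", x$dropped_features$feature[i],
                  x$dropped_features$reason[i]))
  }
  if (length(x$imputed_counts)) {
    cat("  imputed cells:\n")
    for (ind in names(x$imputed_counts))
      cat(sprintf("    %s: %d (%s)\n", ind, x$imputed_counts[[ind]],
                  x$imputation_method[[ind]]))
  }
  invisible(x)
}

#' Exclude subjects with implausibly many exam records
#'
#' Subjects contributing more than `max_exams` records (default 20) are
#' removed entirely; a subject with exactly `max_exams` is retained.
#'
#' @param cohort Cohort data.frame with `subject_id`.
#' @param max_exams Strict upper bound on records per subject.
#' @return List with `data` (filtered cohort) and `report` fragment.
#' @export
exclude_heavy_users <- function(cohort, max_exams = 20) {
  counts <- table(cohort$subject_id)
  keep_ids <- names(counts)[counts <= max_exams]
  out <- cohort[cohort$subject_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  rep <- new_cleaning_report(length(counts), nrow(cohort))
  rep$n_subjects_out <- length(keep_ids)
  rep$n_records_out <- nrow(out)
  list(data = out, report = rep)
}

#' Remove implausible values and over-age records
#'
#' Records with age above `age_max` (strictly) are dropped. Indicator values
#' outside the physician plausibility bounds of the registry are set to
#' missing, keeping the record so the multi-year continuity survives;
#' imputation handles the gap downstream. Indicators without plausibility
#' bounds are left unfiltered with a warning.
#'
#' @param cohort Cohort data.frame.
#' @param registry An `indicator_registry`.
#' @param age_max Maximum allowed age (inclusive), default 80.
#' @return List with `data` and `report` fragment (records dropped,
#'   per-indicator cells blanked).
#' @export
remove_outliers <- function(cohort, registry = default_indicator_registry(),
                            age_max = 80) {
  rep <- new_cleaning_report(length(unique(cohort$subject_id)), nrow(cohort))
  keep <- is.na(cohort$age) | cohort$age <= age_max
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  cells <- integer()
  for (ind in intersect(registry$indicator, names(out))) {
    i <- match(ind, registry$indicator)
    lo <- registry$plaus_lower[i]
    hi <- registry$plaus_upper[i]
    if (is.na(lo) && is.na(hi)) {
      warning("no plausibility bounds for ", ind, "; values not screened")
      next
    }
    bad <- !is.na(out[[ind]]) &
      ((!is.na(lo) & out[[ind]] < lo) | (!is.na(hi) & out[[ind]] > hi))
    if (any(bad)) {
      out[[ind]][bad] <- NA_real_
      cells[[ind]] <- sum(bad)
    }
  }
  rep$n_subjects_out <- length(unique(out$subject_id))
  rep$n_records_out <- nrow(out)
  rep$outlier_cells <- cells
  list(data = out, report = rep)
}

#' Derive waist-to-hip ratio and body-mass index
#'
#' WHR = waist / hip circumference; BMI = weight (kg) / height (m)^2.
#' Computed wherever the raw fields exist; rows with nonpositive
#' denominators get a missing value (with a warning). When the raw fields
#' are absent, pre-existing `WHR`/`BMI` columns pass through unchanged.
#'
#' @param cohort Cohort data.frame; waist circumference is the `WC` column,
#'   hip circumference `hip` (cm), `weight` (kg), `height` (m).
#' @param only_missing Fill only cells where the derived column is missing,
#'   keeping recorded values (used by [clean_cohort()] so the chain is
#'   idempotent after imputation).
#' @return The cohort with `WHR` and `BMI` columns filled.
#' @export
derive_anthropometrics <- function(cohort, only_missing = FALSE) {
  set_col <- function(df, col, new) {
    if (only_missing && col %in% names(df)) {
      fill <- is.na(df[[col]])
      df[[col]][fill] <- new[fill]
    } else df[[col]] <- new
    df
  }
  if (all(c("WC", "hip") %in% names(cohort))) {
    denom_bad <- !is.na(cohort$hip) & cohort$hip <= 0
    if (any(denom_bad)) warning(sum(denom_bad),
                                " record(s) with nonpositive hip; WHR set missing")
    whr <- cohort$WC / cohort$hip
    whr[denom_bad] <- NA_real_
    cohort <- set_col(cohort, "WHR", whr)
  }
  if (all(c("weight", "height") %in% names(cohort))) {
    denom_bad <- !is.na(cohort$height) & cohort$height <= 0
    if (any(denom_bad)) warning(sum(denom_bad),
                                " record(s) with nonpositive height; BMI set missing")
    bmi <- cohort$weight / cohort$height^2
    bmi[denom_bad] <- NA_real_
    cohort <- set_col(cohort, "BMI", bmi)
  }
  cohort
}

# Sample skewness (biased m3 / m2^1.5 form; only its magnitude vs 1 is used).
.skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) return(0)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

# Mean vs median fill: Shapiro-Wilk on a capped subsample; when it rejects,
# fall back on |skewness| > 1 as the practical asymmetry criterion.
.fill_method <- function(x, alpha = 0.05, cap = 5000) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || stats::sd(x) == 0) return("mean")
  xs <- if (length(x) > cap) x[seq(1, length(x), length.out = cap)] else x
  p <- tryCatch(stats::shapiro.test(xs)$p.value, error = function(e) 0)
  if (p >= alpha) return("mean")
  if (abs(.skewness(x)) > 1) "median" else "mean"
}

#' Impute missing indicator values
#'
#' Features with more than `drop_threshold` (default 70%) missing cells are
#' dropped. Remaining gaps are filled per sex (the marginals are
#' sex-stratified) with the mean when the observed distribution is
#' compatible with normality, else the median; see `.fill_method` internals
#' and the vignette for the normal-vs-skewed decision.
#'
#' @param cohort Cohort data.frame with a `sex` column.
#' @param columns Columns to impute; default all registry indicators present.
#' @param registry Used only for the default `columns`.
#' @param alpha Normality-test level (default 0.05).
#' @param drop_threshold Missing-fraction above which a feature is dropped.
#' @param by_sex Compute fill statistics per sex (default) or globally.
#' @return List with `data` (no missing cells left in retained columns) and
#'   `report` fragment.
#' @export
impute_missing <- function(cohort, columns = NULL,
                           registry = default_indicator_registry(),
                           alpha = 0.05, drop_threshold = 0.70,
                           by_sex = TRUE) {
  if (is.null(columns))
    columns <- intersect(registry$indicator, names(cohort))
  rep <- new_cleaning_report(length(unique(cohort$subject_id)), nrow(cohort))
  for (col in columns) {
    frac <- mean(is.na(cohort[[col]]))
    if (frac > drop_threshold) {
      cohort[[col]] <- NULL
      rep$dropped_features <- rbind(rep$dropped_features, data.frame(
        feature = col,
        reason = sprintf("%.0f%% missing (> %.0f%%)", 100 * frac,
                         100 * drop_threshold),
        stringsAsFactors = FALSE))
      next
    }
    miss <- is.na(cohort[[col]])
    if (!any(miss)) next
    method <- .fill_method(cohort[[col]], alpha = alpha)
    fill_stat <- if (method == "mean") mean else stats::median
    if (by_sex && "sex" %in% names(cohort)) {
      for (s in unique(cohort$sex)) {
        sel <- miss & cohort$sex == s
        if (!any(sel)) next
        cohort[[col]][sel] <- fill_stat(cohort[[col]][cohort$sex == s],
                                        na.rm = TRUE)
      }
    } else {
      cohort[[col]][miss] <- fill_stat(cohort[[col]], na.rm = TRUE)
    }
    rep$imputed_counts[[col]] <- sum(miss)
    rep$imputation_method[[col]] <- method
  }
  list(data = cohort, report = rep)
}

# Merge report fragments from the chained stages into one report.
.merge_reports <- function(first, ...) {
  out <- first
  for (r in list(...)) {
    out$n_subjects_out <- r$n_subjects_out
    out$n_records_out <- r$n_records_out
    out$dropped_features <- rbind(out$dropped_features, r$dropped_features)
    out$outlier_cells <- c(out$outlier_cells, r$outlier_cells)
    out$imputed_counts <- c(out$imputed_counts, r$imputed_counts)
    out$imputation_method <- c(out$imputation_method, r$imputation_method)
  }
  out
}

#' Run the full cleaning chain
#'
#' Heavy-user exclusion (> `max_exams` records), outlier screening (age
#' above `age_max` dropped, out-of-plausibility values blanked),
#' WHR/BMI derivation, then drop-and-impute. Running the chain on its own
#' output is a no-op.
#'
#' @inheritParams remove_outliers
#' @inheritParams exclude_heavy_users
#' @inheritParams impute_missing
#' @return List with `data` and a consolidated `report`
#'   ([new_cleaning_report()]).
#' @export
clean_cohort <- function(cohort, registry = default_indicator_registry(),
                         max_exams = 20, age_max = 80, alpha = 0.05,
                         drop_threshold = 0.70, by_sex = TRUE) {
  s1 <- exclude_heavy_users(cohort, max_exams = max_exams)
  s2 <- remove_outliers(s1$data, registry = registry, age_max = age_max)
  s2$data <- derive_anthropometrics(s2$data, only_missing = TRUE)
  s3 <- impute_missing(s2$data, registry = registry, alpha = alpha,
                       drop_threshold = drop_threshold, by_sex = by_sex)
  rep <- .merge_reports(s1$report, s2$report, s3$report)
  rep$n_subjects_in <- s1$report$n_subjects_in
  rep$n_records_in <- s1$report$n_records_in
  list(data = s3$data, report = rep)
}
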