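#' Default sex-specific indicator marginals for the synthetic cohort
#'
#' Mean and standard deviation per indicator and sex describing a large
#' southern-Chinese health-checkup population, used as generation targets.
#' `Age` is the baseline-age distribution (truncated to the 18-80 inclusion
#' window at generation time).
#'
#' @return Data.frame with columns `indicator, male_mean, male_sd,
#'   female_mean, female_sd`.
#' @export
default_marginals <- function() {
  tab <- rbind(
    c("Age",  39.65, 13.33, 37.18, 13.08),
    c("WC",   82.52,  8.12, 75.35,  7.74),
    c("WHR",   0.89,  0.08,  0.82,  0.08),
    c("DBP",  74.95, 10.11, 70.19,  8.98),
    c("SBP", 123.47, 14.23, 115.87, 14.35),
    c("TG",    1.65,  1.43,  1.14,  0.72),
    c("HDLC",  1.29,  0.24,  1.43,  0.28),
    c("LDLC",  3.11,  0.60,  2.95,  0.55),
    c("BMI",  24.03,  3.05, 22.31,  2.82),
    c("TC",    5.20,  0.91,  5.04,  0.85),
    c("FGLU",  5.00,  1.10,  4.86,  0.78),
    c("UA",  403.71, 81.79, 314.65, 66.60),
    c("ALT",  25.99, 14.92, 16.08,  8.80),
    c("AST",  24.02,  7.91, 20.13,  6.06),
    c("HGB", 151.97, 10.64, 133.97, 11.82),
    c("RBC",   5.15,  0.47,  4.65,  0.40),
    c("WBC",   6.72,  1.54,  6.28,  1.39),
    c("PLT", 239.78, 48.54, 256.88, 53.47),
    c("CR",   77.63, 15.18, 58.15, 13.67))
  out <- data.frame(indicator = tab[, 1],
                    male_mean = as.numeric(tab[, 2]),
                    male_sd = as.numeric(tab[, 3]),
                    female_mean = as.numeric(tab[, 4]),
                    female_sd = as.numeric(tab[, 5]),
                    stringsAsFactors = FALSE)
  out
}

# Mean/sd of a normal(mu, sigma) truncated to [lo, hi].
.trunc_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  ada <- if (is.finite(a)) a * da else 0
  bdb <- if (is.finite(b)) b * db else 0
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (ada - bdb) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Underlying (mu, sigma) such that the [lo,hi]-truncated normal has the
# requested mean and sd. Returns the request unchanged when truncation is
# negligible (< 1e-4 tail mass).
.match_truncnorm <- function(target_mean, target_sd, lo = 0, hi = Inf) {
  ptail <- stats::pnorm(lo, target_mean, target_sd) +
    stats::pnorm(hi, target_mean, target_sd, lower.tail = FALSE)
  if (ptail < 1e-4)
    return(c(mu = target_mean, sigma = target_sd))
  obj <- function(par) {
    mm <- .trunc_moments(par[1], exp(par[2]), lo, hi)
    (mm["mean"] - target_mean)^2 / target_sd^2 +
      (mm["sd"] - target_sd)^2 / target_sd^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Quantile of the truncated normal.
.qtrunc <- function(p, mu, sigma, lo = 0, hi = Inf) {
  pa <- stats::pnorm(lo, mu, sigma)
  pb <- stats::pnorm(hi, mu, sigma)
  stats::qnorm(pa + p * (pb - pa), mu, sigma)
}

#' Configuration for the synthetic longitudinal cohort
#'
#' Describes the generated study population: sex-specific marginals per
#' indicator, within-subject lag-1 autocorrelation, and a "drifting"
#' subpopulation whose MetS-component indicators (WC, SBP, DBP, TG, FGLU
#' rising; HDL-C falling) deteriorate linearly year over year, producing
#' incident MetS cases in the label year.
#'
#' When `drift_fraction` is `NA` (the default) it is calibrated at
#' generation time by bisection on a pilot sample so that the realized
#' window-level incidence matches `target_incidence`; the calibration
#' adjusts the generating process, never the labels.
#'
#' @param n_subjects Number of subjects.
#' @param n_years Exam years per subject (default 5).
#' @param sex_ratio Fraction male (default 0.57, the male share of the
#'   checkup population the marginals describe).
#' @param seed Integer RNG seed; the cohort is a deterministic function of
#'   the full config.
#' @param marginals Data.frame as [default_marginals()].
#' @param rho Within-subject lag-1 autocorrelation, scalar or named
#'   per-indicator vector; the default [default_autocorrelation()] uses
#'   literature-plausible tracking correlations (anthropometrics high,
#'   blood pressure low) — an assumption, see the vignette.
#' @param drift_fraction Fraction of subjects on a deteriorating trajectory,
#'   in (0,1), or `NA` to calibrate against `target_incidence`.
#' @param drift_magnitude First-year mean shift of a drifting subject's
#'   MetS-component indicators, in sex-specific SD units (default 0.5).
#'   Deterioration starts at a random onset year (uniform over years
#'   2..`n_years`) and accelerates: the annual increment grows by the
#'   factor `drift_accel` each year after onset, mimicking the late,
#'   accelerating decline that precedes incident MetS rather than a
#'   life-long elevated level.
#' @param drift_accel Yearly growth factor of the deterioration increment
#'   (default 1.6).
#' @param target_incidence Target fraction of prediction windows labeled 1
#'   (default 0.085).
#' @param lognormal Character vector of indicators to draw from a
#'   moment-matched log-normal instead of a truncated normal (for
#'   right-skewed markers such as TG); default none.
#' @param start_year First calendar exam year (default 2015).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects, n_years = 5, sex_ratio = 0.57,
                          seed = 1, marginals = default_marginals(),
                          rho = default_autocorrelation(),
                          drift_fraction = NA_real_,
                          drift_magnitude = 0.5, drift_accel = 1.6,
                          target_incidence = 0.085,
                          lognormal = character(0), start_year = 2015) {
  stopifnot(n_subjects >= 2, n_years >= 1)
  if (!is.na(drift_fraction) &&
      (drift_fraction <= 0 || drift_fraction >= 1))
    stop("drift_fraction must lie strictly between 0 and 1 (or NA)")
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1")
  if (target_incidence <= 0 || target_incidence >= 1)
    stop("target_incidence must lie in (0,1)")
  sd_cols <- c("male_sd", "female_sd")
  if (any(unlist(marginals[sd_cols]) <= 0)) stop("all SDs must be > 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_years = as.integer(n_years), sex_ratio = sex_ratio,
                 seed = as.integer(seed), marginals = marginals, rho = rho,
                 drift_fraction = drift_fraction,
                 drift_magnitude = drift_magnitude,
                 drift_accel = drift_accel,
                 target_incidence = target_incidence,
                 lognormal = lognormal,
                 start_year = as.integer(start_year)),
            class = "cohort_config")
}

#' Default within-subject lag-1 autocorrelations
#'
#' Year-to-year tracking correlations per indicator: anthropometric traits
#' (WC, BMI, HGB, PLT, ...) track tightly, blood pressure is the most
#' variable, lipids, glucose and enzymes sit in between. These are
#' assumptions chosen for realism (the source marginals carry no
#' longitudinal information); see the vignette.
#'
#' @return Named numeric vector with a `default` entry for unlisted
#'   indicators.
#' @export
default_autocorrelation <- function() {
  c(WC = 0.90, WHR = 0.85, BMI = 0.92, SBP = 0.65, DBP = 0.65,
    TG = 0.70, HDLC = 0.75, LDLC = 0.75, TC = 0.75, FGLU = 0.70,
    UA = 0.80, ALT = 0.70, AST = 0.70, HGB = 0.85, RBC = 0.85,
    WBC = 0.75, PLT = 0.85, CR = 0.80, default = 0.75)
}

.rho_for <- function(config, indicator) {
  r <- config$rho
  if (length(r) == 1 && is.null(names(r))) return(unname(r))
  if (!is.null(names(r)) && indicator %in% names(r))
    return(unname(r[indicator]))
  if (!is.null(names(r)) && "default" %in% names(r))
    return(unname(r["default"]))
  unname(r[1])
}

# Indicators shifted for drifting subjects, with drift sign.
.drift_signs <- function() {
  c(WC = 1, SBP = 1, DBP = 1, TG = 1, FGLU = 1, HDLC = -1)
}

# Standard-normal AR(1) paths, n subjects x n_years.
.ar1_matrix <- function(n, n_years, rho) {
  Z <- matrix(0, n, n_years)
  Z[, 1] <- stats::rnorm(n)
  if (n_years > 1) {
    for (t in 2:n_years)
      Z[, t] <- rho * Z[, t - 1] + sqrt(1 - rho^2) * stats::rnorm(n)
  }
  Z
}

# Core generator; assumes drift_fraction is resolved (non-NA).
.generate_cohort_core <- function(config) {
  n <- config$n_subjects
  ny <- config$n_years
  marg <- config$marginals
  set.seed(config$seed)

  n_male <- round(n * config$sex_ratio)
  sex <- rep(c("male", "female"), c(n_male, n - n_male))

  # Baseline age, truncated so the oldest exam stays within the 18-80 window.
  age_hi <- 80 - (ny - 1)
  z_age <- stats::rnorm(n)
  age1 <- numeric(n)
  arow <- marg[marg$indicator == "Age", ]
  for (s in c("male", "female")) {
    idx <- sex == s
    if (!any(idx)) next
    m <- if (s == "male") arow$male_mean else arow$female_mean
    sd <- if (s == "male") arow$male_sd else arow$female_sd
    par <- .match_truncnorm(m, sd, lo = 18, hi = age_hi)
    age1[idx] <- .qtrunc(stats::pnorm(z_age[idx]), par["mu"], par["sigma"],
                         lo = 18, hi = age_hi)
  }
  age1 <- round(age1)

  # Height: subject-constant latent so weight = BMI * height^2 is coherent.
  z_h <- stats::rnorm(n)
  height <- ifelse(sex == "male", 1.70 + 0.065 * z_h, 1.58 + 0.060 * z_h)
  height <- pmin(pmax(height, 1.30), 2.20)

  drift <- stats::runif(n) < config$drift_fraction
  # Deterioration onset (uniform over years 2..ny) and cumulative shift in
  # SD units per year: increments of drift_magnitude growing by drift_accel
  # each year after onset. Drawn for every subject to keep the RNG stream
  # independent of the drift assignment.
  onset <- if (ny >= 2) sample(2:ny, n, replace = TRUE) else rep(2L, n)
  shift_sd <- matrix(0, n, ny)
  for (t in seq_len(ny)) {
    el <- t - onset  # years elapsed since onset
    active <- drift & el >= 0
    if (config$drift_accel == 1) cum <- (el + 1)
    else cum <- (config$drift_accel^(el + 1) - 1) / (config$drift_accel - 1)
    shift_sd[active, t] <- config$drift_magnitude * cum[active]
  }

  inds <- setdiff(marg$indicator, "Age")
  vals <- vector("list", length(inds))
  names(vals) <- inds
  signs <- .drift_signs()
  for (ind in inds) {
    row <- marg[marg$indicator == ind, ]
    Z <- .ar1_matrix(n, ny, .rho_for(config, ind))
    V <- matrix(NA_real_, n, ny)
    sd_by_subj <- numeric(n)
    for (s in c("male", "female")) {
      idx <- sex == s
      if (!any(idx)) next
      m <- if (s == "male") row$male_mean else row$female_mean
      sd <- if (s == "male") row$male_sd else row$female_sd
      sd_by_subj[idx] <- sd
      if (ind %in% config$lognormal) {
        s2 <- log(1 + sd^2 / m^2)
        V[idx, ] <- exp(log(m) - s2 / 2 + sqrt(s2) * Z[idx, ])
      } else {
        par <- .match_truncnorm(m, sd, lo = 0)
        V[idx, ] <- .qtrunc(stats::pnorm(Z[idx, ]), par["mu"], par["sigma"],
                            lo = 0)
      }
    }
    if (ind %in% names(signs) && any(drift) && config$drift_magnitude != 0) {
      V[drift, ] <- V[drift, ] +
        signs[[ind]] * sd_by_subj[drift] * shift_sd[drift, , drop = FALSE]
      V <- pmax(V, 0.01)
    }
    vals[[ind]] <- V
  }

  # Derived-anthropometrics coherence: hip from WC/WHR, weight from BMI.
  hip <- vals$WC / vals$WHR
  weight <- vals$BMI * height^2

  out <- data.frame(
    subject_id = rep(sprintf("S%06d", seq_len(n)), each = ny),
    sex = rep(sex, each = ny),
    age = as.integer(rep(age1, each = ny) + rep(seq_len(ny) - 1, n)),
    year = rep(config$start_year + seq_len(ny) - 1, n),
    height = rep(height, each = ny),
    weight = as.vector(t(weight)),
    hip = as.vector(t(hip)),
    stringsAsFactors = FALSE)
  for (ind in inds) out[[ind]] <- as.vector(t(vals[[ind]]))
  attr(out, "drift") <- stats::setNames(drift, sprintf("S%06d", seq_len(n)))
  attr(out, "config") <- config
  out
}

# Bisection on drift_fraction against the realized window incidence of a
# pilot cohort generated with common random numbers (same pilot seed for
# every candidate), which makes incidence monotone in the fraction.
.calibrate_drift_fraction <- function(config, pilot_n = 2000, iters = 14) {
  pilot_seed <- (config$seed %% 100003L) * 7L + 13L
  pilot <- function(f) {
    cfg <- config
    cfg$n_subjects <- as.integer(min(pilot_n, config$n_subjects))
    cfg$drift_fraction <- f
    cfg$seed <- pilot_seed
    w <- build_windows(.generate_cohort_core(cfg))
    unname(w$counts["n_positive"] / max(w$counts["n_total"], 1))
  }
  target <- config$target_incidence
  inc0 <- pilot(1e-9)
  if (inc0 > target) {
    stop("target_incidence ", target, " infeasible: baseline incidence ",
         "with no drifting subpopulation is already ", round(inc0, 4),
         "; lower the marginals' overlap with the diagnostic thresholds ",
         "or raise target_incidence")
  }
  f_hi <- 0.95
  inc_hi <- pilot(f_hi)
  if (inc_hi < target)
    stop("target_incidence ", target, " infeasible: incidence at ",
         "drift_fraction 0.95 is only ", round(inc_hi, 4),
         "; increase drift_magnitude")
  f_lo <- 0
  for (i in seq_len(iters)) {
    f_mid <- (f_lo + f_hi) / 2
    if (pilot(f_mid) < target) f_lo <- f_mid else f_hi <- f_mid
  }
  (f_lo + f_hi) / 2
}

#' Generate a synthetic longitudinal exam cohort
#'
#' Draws, per subject, `n_years` consecutive annual exam records. Marginals
#' per sex are moment-matched truncated normals (truncated at physiologic
#' floors), within-subject trajectories follow a Gaussian-copula AR(1) with
#' lag-1 correlation `rho`, and a `drift_fraction` subpopulation
#' deteriorates linearly on the MetS-component indicators. Hip circumference
#' and weight are derived from latent WC/WHR and BMI/height so that
#' recomputing WHR and BMI from raw anthropometrics is coherent.
#'
#' @param config A [cohort_config()].
#' @return Data.frame, one row per subject-year, columns `subject_id, sex,
#'   age, year, height, weight, hip` plus the 18 indicators. The drifting
#'   subjects are recorded in `attr(, "drift")`; the resolved config
#'   (including any calibrated `drift_fraction`) in `attr(, "config")`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.na(config$drift_fraction))
    config$drift_fraction <- .calibrate_drift_fraction(config)
  .generate_cohort_core(config)
}

#' Inject missing-completely-at-random cells into a cohort table
#'
#' @param cohort Cohort data.frame from [generate_cohort()].
#' @param rates Named vector, indicator -> missingness fraction in \[0,1\].
#' @param seed Integer seed.
#' @return The cohort with the selected cells set `NA`.
#' @export
inject_missingness <- function(cohort, rates, seed = 1) {
  if (any(rates < 0 | rates > 1))
    stop("missingness rates must lie in [0, 1]")
  bad <- setdiff(names(rates), names(cohort))
  if (length(bad)) stop("unknown indicator(s): ", paste(bad, collapse = ", "))
  set.seed(seed)
  for (ind in names(rates)) {
    hit <- stats::runif(nrow(cohort)) < rates[[ind]]
    cohort[[ind]][hit] <- NA_real_
  }
  cohort
}

#' Write / read a cohort as CSV
#'
#' `format = "wide"` writes one row per subject-year with one column per
#' indicator; `"long"` writes `subject_id, sex, age, year, indicator, value`
#' rows. Missing values are empty cells. Writing is deterministic: the same
#' table produces byte-identical files.
#'
#' @param cohort Cohort data.frame.
#' @param path Output file.
#' @param format `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (format == "long") {
    id_cols <- intersect(c("subject_id", "sex", "age", "year"),
                         names(cohort))
    val_cols <- setdiff(names(cohort), id_cols)
    long <- do.call(rbind, lapply(val_cols, function(v)
      data.frame(cohort[id_cols], indicator = v, value = cohort[[v]],
                 stringsAsFactors = FALSE)))
    long <- long[order(long$subject_id, long$year, long$indicator), ]
    utils::write.csv(long, path, row.names = FALSE, na = "")
  } else {
    utils::write.csv(cohort, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param file CSV file to read.
#' @export
read_cohort_csv <- function(file, format = c("wide", "long")) {
  format <- match.arg(format)
  df <- utils::read.csv(file, stringsAsFactors = FALSE, na.strings = "")
  if (format == "long") {
    wide <- stats::reshape(df, idvar = c("subject_id", "sex", "age", "year"),
                           timevar = "indicator", direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    rownames(wide) <- NULL
    df <- wide
  }
  df
}
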