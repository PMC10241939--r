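#' Sigmoid risk weight
#'
#' `S(x) = 1 / (1 + exp(-a x))` on the scaled risk distance `x`: continuous,
#' strictly increasing, with `S(0) = 0.5` exactly at the normal-range limit.
#' Values are clamped to the open interval (0, 1) so extreme arguments
#' cannot produce 0/1 or overflow.
#'
#' @param x_scaled Scaled risk distance (see [scale_x()]); any numeric.
#' @param a Steepness parameter, > 0 (default 50, chosen together with the
#'   1/`scale_max` normalization of `x`).
#' @return Numeric in (0, 1), same length as `x_scaled`.
#' @export
sigmoid_weight <- function(x_scaled, a = 50) {
  if (a <= 0) stop("a must be > 0")
  s <- 1 / (1 + exp(-a * x_scaled))
  pmin(pmax(s, 1e-15), 1 - 1e-15)
}

#' Scaled risk distance from the normal-range limit
#'
#' The raw distance is `value - limit` for indicators where high values are
#' risky, and `limit - value` for deficit-type indicators (HDL-C), so the
#' clinically risky side is always positive. Dividing by the per-indicator
#' `scale_max` puts indicators with different units on a common scale
#' before the sigmoid.
#'
#' @param value Current-year indicator value(s).
#' @param limit Risk-direction normal-range limit (same units).
#' @param risk_direction `"high_is_risk"` or `"low_is_risk"`.
#' @param scale_max Positive scaling constant.
#' @return Scaled signed distance, positive on the risky side.
#' @export
scale_x <- function(value, limit, risk_direction = "high_is_risk",
                    scale_max = 1) {
  if (any(is.na(limit))) stop("missing normal-range limit")
  if (any(scale_max <= 0)) stop("scale_max must be > 0")
  raw <- if (risk_direction == "low_is_risk") limit - value else value - limit
  raw / scale_max
}

#' Year-to-year numerical difference (DNF)
#'
#' @param i_prev,i_curr Indicator values in the earlier and later year.
#' @return `i_curr - i_prev`.
#' @export
compute_dnf <- function(i_prev, i_curr) {
  i_curr - i_prev
}

#' Year-to-year state difference (DSF)
#'
#' The abnormal/normal state per year (1 = beyond the risk-direction normal
#' limit) differenced across consecutive years: +1 normal-to-abnormal,
#' -1 abnormal-to-normal, 0 no change. The state uses the same abnormality
#' convention as [flag_abnormal_original()].
#'
#' @inheritParams compute_dnf
#' @inheritParams scale_x
#' @param inclusive Treat the limit itself as abnormal (used for the MetS
#'   diagnostic indicators, whose printed thresholds are inclusive).
#' @return Integer in -1, 0, +1.
#' @export
compute_dsf <- function(i_prev, i_curr, limit,
                        risk_direction = "high_is_risk",
                        inclusive = FALSE) {
  st <- function(v) as.integer(flag_abnormal_original(v, limit,
                                                      risk_direction,
                                                      inclusive))
  st(i_curr) - st(i_prev)
}

# Interval terms and combined value for a block of 4-year series.
# values: n x 4 matrix; limit: scalar or length-n; returns list(g, f, x, dnf).
.dff_terms <- function(values, limit, risk_direction, scale_max, a, b,
                       renormalize = FALSE) {
  stopifnot(ncol(values) == 4)
  dnf <- values[, 2:4, drop = FALSE] - values[, 1:3, drop = FALSE]
  # risk distance evaluated at the later year of each interval
  x <- vapply(2:4, function(j)
    scale_x(values[, j], limit, risk_direction, scale_max),
    numeric(nrow(values)))
  if (nrow(values) == 1L) x <- matrix(x, nrow = 1)
  s <- sigmoid_weight(x, a = a)
  f <- dnf * s
  w <- c(b^3, b^2, b)
  if (renormalize) w <- w / sum(w)
  g <- as.vector(f %*% w)
  list(g = g, f = f, x = x, dnf = dnf)
}

#' Differential fluctuant feature (DFF) for one 4-year series
#'
#' Each of the three consecutive-year differences is weighted by the
#' sigmoid of the scaled risk distance at the later year of its interval,
#' then the three terms are combined with geometric decay weights `b^3,
#' b^2, b` (oldest to newest), so recent change near the normal limit
#' dominates:
#' `g = b^3 f1 + b^2 f2 + b f3`, `f_i = (v_{i+1} - v_i) * S(x_{i+1})`.
#'
#' @param values Numeric length-4 vector (years 1-4, oldest first), or an
#'   n x 4 matrix of series.
#' @param limit Risk-direction normal limit (scalar, or length n for
#'   sex-specific limits).
#' @param risk_direction `"high_is_risk"` or `"low_is_risk"`.
#' @param scale_max Positive scaling constant for the risk distance.
#' @param a Sigmoid steepness (default 50).
#' @param b Decay parameter in (0, 1), default 0.6.
#' @param renormalize Divide the weights by `b^3 + b^2 + b` so they sum to
#'   1 (default `FALSE`, the literal combination).
#' @return For a vector input, a list with `g`, the three `terms`
#'   (data.frame: interval, dnf, x, s, f) and the parameters; for a matrix,
#'   the numeric vector of `g` values.
#' @export
compute_dff <- function(values, limit, risk_direction = "high_is_risk",
                        scale_max = 1, a = 50, b = 0.6,
                        renormalize = FALSE) {
  if (b <= 0 || b >= 1) stop("b must lie in (0, 1)")
  vec_in <- is.null(dim(values))
  if (vec_in) {
    if (length(values) != 4) stop("a series must hold 4 annual values")
    values <- matrix(values, nrow = 1)
  }
  if (anyNA(values)) stop("missing year in series; impute or drop upstream")
  res <- .dff_terms(values, limit, risk_direction, scale_max, a, b,
                    renormalize)
  if (!vec_in) return(res$g)
  list(g = res$g[1],
       terms = data.frame(interval = c("y1_y2", "y2_y3", "y3_y4"),
                          dnf = res$dnf[1, ], x = res$x[1, ],
                          s = sigmoid_weight(res$x[1, ], a = a),
                          f = res$f[1, ]),
       a = a, b = b, renormalize = renormalize)
}

#' Abnormal-state flag for a DNF value
#'
#' A year-to-year difference is abnormal when strictly positive (the value
#' moved upward; for deficit-type indicators the DNF is computed on the
#' risk-oriented scale upstream).
#'
#' @param dnf Numeric vector of DNF values.
#' @return Logical vector.
#' @export
flag_abnormal_dnf <- function(dnf) {
  dnf > 0
}

#' Abnormal-state flags for a population of DFF values
#'
#' A DFF is abnormal when its absolute value strictly exceeds the
#' population mean of absolute values for that indicator.
#'
#' @param g Numeric vector: the DFF values of one indicator across the
#'   analysis cohort.
#' @return Logical vector, same length.
#' @export
flag_abnormal_dff <- function(g) {
  g <- as.numeric(g)
  if (!length(g)) stop("empty DFF population")
  abs(g) > mean(abs(g), na.rm = TRUE)
}

#' Freeze per-indicator scaling constants from a training cohort
#'
#' Sets `scale_max` in the registry to the maximum absolute risk distance
#' observed in the data, so that the x-scaling is a fixed, pure function at
#' prediction time.
#'
#' @param registry An `indicator_registry`.
#' @param data Exam table or window table: either indicator columns or
#'   `{IND}_y1..y4` columns, plus `sex`.
#' @param overwrite Replace already-set `scale_max` values (default FALSE).
#' @return The registry with `scale_max` filled.
#' @export
freeze_scale_max <- function(registry, data, overwrite = FALSE) {
  for (i in seq_len(nrow(registry))) {
    ind <- registry$indicator[i]
    if (!overwrite && !is.na(registry$scale_max[i])) next
    cols <- intersect(c(ind, sprintf("%s_y%d", ind, 1:4)), names(data))
    if (!length(cols)) next
    lim <- indicator_limit_vec(registry, ind, data$sex)
    raw <- unlist(lapply(cols, function(cl)
      if (registry$risk_direction[i] == "low_is_risk")
        lim - data[[cl]] else data[[cl]] - lim))
    m <- max(abs(raw), na.rm = TRUE)
    registry$scale_max[i] <- if (is.finite(m) && m > 0) m else 1
  }
  registry
}

#' Assemble the modeling feature matrix from window samples
#'
#' Builds, per indicator, the requested feature groups: the four original
#' annual values (`{IND}_y1..y4`), the three year-to-year numeric
#' differences (`{IND}_DNF1..3`), the three state differences
#' (`{IND}_DSF1..3`) and the combined differential fluctuant feature
#' (`{IND}_DFF`), plus age at the label year and a male indicator. The
#' column-to-group map is stored in `attr(, "provenance")`; the scaling
#' constants actually used in `attr(, "scale_max")`.
#'
#' @param windows Output of [build_windows()] (or its `samples` frame).
#' @param registry An `indicator_registry`; `scale_max` entries that are
#'   `NA` are frozen from these windows ([freeze_scale_max()]).
#' @param sets Feature groups to include, subset of
#'   `c("original", "dnf", "dsf", "dff")`.
#' @param a,b,renormalize DFF parameters, see [compute_dff()].
#' @return Data.frame with the feature columns plus `ms_result`.
#' @export
build_feature_matrix <- function(windows,
                                 registry = default_indicator_registry(),
                                 sets = c("original", "dnf", "dsf", "dff"),
                                 a = 50, b = 0.6, renormalize = FALSE) {
  sets <- match.arg(sets, several.ok = TRUE)
  samples <- if (is.data.frame(windows)) windows else windows$samples
  if (!nrow(samples)) stop("no window samples")
  inds <- mets_indicators()
  inds <- inds[vapply(inds, function(i)
    all(sprintf("%s_y%d", i, 1:4) %in% names(samples)), logical(1))]
  if (!length(inds)) stop("no {IND}_y1..y4 columns found")
  registry <- freeze_scale_max(registry, samples)

  out <- data.frame(age = samples$age_at_label,
                    sex_male = as.integer(samples$sex == "male"))
  prov <- c(age = "demographic", sex_male = "demographic")
  inclusive_set <- mets_core_indicators()
  for (ind in inds) {
    ri <- match(ind, registry$indicator)
    dir <- registry$risk_direction[ri]
    lim <- indicator_limit_vec(registry, ind, samples$sex)
    smax <- registry$scale_max[ri]
    vals <- as.matrix(samples[sprintf("%s_y%d", ind, 1:4)])
    if ("original" %in% sets) {
      for (k in 1:4) {
        cn <- sprintf("%s_y%d", ind, k)
        out[[cn]] <- vals[, k]
        prov[[cn]] <- sprintf("original_y%d", k)
      }
    }
    need_delta <- any(c("dnf", "dsf", "dff") %in% sets)
    if (need_delta) {
      terms <- .dff_terms(vals, lim, dir, smax, a, b, renormalize)
      if ("dnf" %in% sets) {
        for (k in 1:3) {
          cn <- sprintf("%s_DNF%d", ind, k)
          out[[cn]] <- terms$dnf[, k]
          prov[[cn]] <- "DNF"
        }
      }
      if ("dsf" %in% sets) {
        incl <- ind %in% inclusive_set
        state <- vapply(1:4, function(k)
          as.integer(flag_abnormal_original(vals[, k], lim, dir,
                                            inclusive = incl)),
          integer(nrow(vals)))
        if (nrow(vals) == 1L) state <- matrix(state, nrow = 1)
        for (k in 1:3) {
          cn <- sprintf("%s_DSF%d", ind, k)
          out[[cn]] <- state[, k + 1] - state[, k]
          prov[[cn]] <- "DSF"
        }
      }
      if ("dff" %in% sets) {
        cn <- sprintf("%s_DFF", ind)
        out[[cn]] <- terms$g
        prov[[cn]] <- "DFF"
      }
    }
  }
  out$ms_result <- samples$ms_result
  attr(out, "provenance") <- prov
  attr(out, "scale_max") <- stats::setNames(
    registry$scale_max[match(inds, registry$indicator)], inds)
  attr(out, "dff_params") <- list(a = a, b = b, renormalize = renormalize)
  out
}
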