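# Temporal feature constructions: sigmoid weight, risk distance, DNF, DSF,
# DFF with geometric decay, and the abnormal-state flags.

test_that("sigmoid weight is centered at one half and saturates safely", {
  for (a in c(1, 50, 500)) expect_identical(sigmoid_weight(0, a), 0.5)
  expect_lt(sigmoid_weight(-1e6, 50), 1e-10)
  expect_gt(sigmoid_weight(1e6, 50), 1 - 1e-10)
  s <- sigmoid_weight(c(-1e308, 1e308), 50)
  expect_true(all(s > 0 & s < 1))
  # closed-form oracle: x = -0.02, a = 50 -> 1 / (1 + e^1)
  expect_equal(sigmoid_weight(-0.02, 50), 1 / (1 + exp(1)),
               tolerance = 1e-12)
  x <- seq(-0.2, 0.2, by = 0.01)
  expect_true(all(diff(sigmoid_weight(x, 50)) > 0))
  expect_error(sigmoid_weight(0, a = -1), "a must")
})

test_that("risk distance is signed toward the risky side and scaled", {
  expect_equal(scale_x(1.70, 1.70, "high_is_risk", 1), 0)
  expect_identical(sigmoid_weight(scale_x(1.70, 1.70)), 0.5)
  # deficit-type indicator: lower HDL-C must land on the positive side
  expect_equal(scale_x(0.90, 1.04, "low_is_risk", 1), 0.14,
               tolerance = 1e-12)
  expect_equal(scale_x(5, 0, "high_is_risk", 10), 0.5)
  expect_error(scale_x(1, NA), "limit")
  expect_error(scale_x(1, 1, scale_max = 0), "scale_max")
})

test_that("risk-direction reflection leaves the distance magnitude unchanged", {
  set.seed(2)
  v <- runif(100, 0, 4)
  lim <- 1.5
  x_hi <- scale_x(v, lim, "high_is_risk", 2)
  x_lo <- scale_x(2 * lim - v, lim, "low_is_risk", 2)
  expect_equal(abs(x_hi), abs(x_lo), tolerance = 1e-12)
})

test_that("year-to-year differences follow the current-minus-past convention", {
  expect_equal(compute_dnf(1.2, 1.8), 0.6)
  expect_equal(compute_dnf(3.3, 3.3), 0)
  expect_equal(compute_dnf(2.0, 1.5), -0.5)
})

test_that("state differences take values in -1, 0, +1", {
  expect_equal(compute_dsf(1.5, 2.0, limit = 1.70), 1L)   # normal->abnormal
  expect_equal(compute_dsf(2.0, 1.9, limit = 1.70), 0L)   # stays abnormal
  expect_equal(compute_dsf(2.0, 1.5, limit = 1.70), -1L)  # back to normal
  expect_equal(compute_dsf(1.20, 0.95, limit = 1.04,
                           risk_direction = "low_is_risk"), 1L)
})

test_that("constant series give zero DFF; recent jumps outweigh old ones", {
  expect_equal(compute_dff(rep(2.2, 4), limit = 1.7)$g, 0)
  old_jump <- compute_dff(c(1.0, 1.6, 1.6, 1.6), limit = 1.7,
                          scale_max = 1)$g
  new_jump <- compute_dff(c(1.0, 1.0, 1.0, 1.6), limit = 1.7,
                          scale_max = 1)$g
  expect_gt(abs(new_jump), abs(old_jump))
  expect_error(compute_dff(c(1, 2, 3), limit = 1), "4 annual")
  expect_error(compute_dff(c(1, 2, 3, NA), limit = 1), "missing")
  expect_error(compute_dff(1:4, limit = 1, b = 1.2), "b must")
})

test_that("the TG worked example matches an independent hand computation", {
  v <- c(1.0, 1.2, 1.5, 1.9)
  lim <- 1.70
  smax <- max(abs(v - lim))          # 0.7, the frozen-scale convention
  # term-by-term arithmetic, written out without the package helpers
  sig <- function(z) 1 / (1 + exp(-50 * z))
  f1 <- (1.2 - 1.0) * sig((1.2 - lim) / smax)
  f2 <- (1.5 - 1.2) * sig((1.5 - lim) / smax)
  f3 <- (1.9 - 1.5) * sig((1.9 - lim) / smax)
  expected <- 0.6^3 * f1 + 0.6^2 * f2 + 0.6 * f3
  got <- compute_dff(v, limit = lim, scale_max = smax, a = 50, b = 0.6)
  expect_equal(got$g, expected, tolerance = 1e-12)
  expect_equal(got$terms$f, c(f1, f2, f3), tolerance = 1e-12)
  # the optional renormalization divides by b^3 + b^2 + b
  ren <- compute_dff(v, limit = lim, scale_max = smax, renormalize = TRUE)
  expect_equal(ren$g, expected / (0.6^3 + 0.6^2 + 0.6), tolerance = 1e-12)
})

test_that("vectorized DFF agrees with a naive per-series loop on random data", {
  set.seed(31)
  n <- 1000
  V <- matrix(runif(4 * n, 0.5, 3.0), n, 4)
  lim <- 1.70
  smax <- 2.5
  naive <- numeric(n)
  for (i in seq_len(n)) {
    g <- 0
    w <- c(0.6^3, 0.6^2, 0.6)
    for (k in 1:3) {
      dnf <- V[i, k + 1] - V[i, k]
      s <- 1 / (1 + exp(-50 * (V[i, k + 1] - lim) / smax))
      g <- g + w[k] * dnf * s
    }
    naive[i] <- g
  }
  fast <- compute_dff(V, limit = lim, scale_max = smax)
  expect_equal(fast, naive, tolerance = 1e-12)
})

test_that("a rising value on the risk side strictly increases its term", {
  # same positive change, later-year value moving up the risk scale
  lim <- 1.7
  f_at <- function(v4) {
    d <- compute_dff(c(1.0, 1.0, v4 - 0.3, v4), limit = lim, scale_max = 1)
    d$terms$f[3]
  }
  vals <- seq(1.2, 2.4, by = 0.2)
  expect_true(all(diff(vapply(vals, f_at, numeric(1))) > 0))
})

test_that("abnormality flags for DNF and DFF follow their definitions", {
  expect_identical(flag_abnormal_dnf(c(0.3, 0, -0.3)),
                   c(TRUE, FALSE, FALSE))
  expect_identical(flag_abnormal_dff(c(1, 1, 4)), c(FALSE, FALSE, TRUE))
  expect_identical(flag_abnormal_dff(c(2, 2, 2)), rep(FALSE, 3))
  expect_identical(flag_abnormal_dff(c(0, 0, 0, 9)),
                   c(FALSE, FALSE, FALSE, TRUE))
  expect_error(flag_abnormal_dff(numeric(0)), "empty")
})

test_that("the feature matrix carries the requested groups with provenance", {
  co <- small_cohort()
  w <- build_windows(co)
  fm <- build_feature_matrix(w)
  prov <- attr(fm, "provenance")
  expect_equal(sum(prov == "DFF"), 18)
  expect_equal(sum(prov == "DNF"), 54)
  expect_equal(sum(prov == "DSF"), 54)
  expect_equal(sum(grepl("^original_y", prov)), 72)
  expect_true(all(names(prov) %in% names(fm)))
  expect_false(anyNA(fm))
  smax <- attr(fm, "scale_max")
  expect_true(all(smax > 0))
  # original-only matrix is a column subset
  fm_o <- build_feature_matrix(w, sets = "original")
  expect_true(all(names(fm_o) %in% names(fm)))
  expect_equal(fm_o$TG_y4, fm$TG_y4)
  # spot check one DFF column against the scalar path
  reg <- freeze_scale_max(default_indicator_registry(), w$samples)
  i <- 17
  lim <- if (w$samples$sex[i] == "male") 90 else 85
  ref <- compute_dff(as.numeric(w$samples[i, sprintf("WC_y%d", 1:4)]),
                     limit = lim,
                     scale_max = reg$scale_max[reg$indicator == "WC"])
  expect_equal(fm$WC_DFF[i], ref$g, tolerance = 1e-12)
})
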