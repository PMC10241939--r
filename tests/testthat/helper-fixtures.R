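# Shared fixture builders: all fixtures are constructed in code.

# One clearly healthy male person-year; override fields as needed.
healthy_record <- function(...) {
  rec <- list(sex = "male", WC = 80, FGLU = 5.0, SBP = 118, DBP = 75,
              TG = 1.2, HDLC = 1.40)
  utils::modifyList(rec, list(...))
}

# A subject's exam table over consecutive years; `values` is a named list of
# per-year vectors (recycled). Defaults give a healthy male series.
subject_series <- function(id = "S1", sex = "male", years = 2015:2019,
                           age0 = 40, values = list()) {
  n <- length(years)
  base <- list(WC = 80, FGLU = 5.0, SBP = 118, DBP = 75, TG = 1.2,
               HDLC = 1.40)
  base <- utils::modifyList(base, values)
  df <- data.frame(subject_id = id, sex = sex,
                   age = age0 + seq_len(n) - 1, year = years,
                   stringsAsFactors = FALSE)
  for (v in names(base)) df[[v]] <- rep_len(base[[v]], n)
  df
}

# A small generated cohort shared by several expensive tests.
small_cohort <- local({
  cache <- NULL
  function(n = 1500, seed = 42, ...) {
    if (is.null(cache)) {
      cache <<- generate_cohort(cohort_config(n, seed = seed, ...))
    }
    cache
  }
})

# Separable two-class feature matrix for classifier smoke tests.
separable_features <- function(n = 400, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  data.frame(f1 = y * 3 + rnorm(n, sd = 0.3),
             f2 = rnorm(n),
             ms_result = y)
}
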