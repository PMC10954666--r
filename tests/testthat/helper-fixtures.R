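# Shared test fixtures. Larger simulated objects are built once per run
# and memoized so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the standard large fixture + fitted generator + synthetic sample
big_fixture <- function() {
  cached("big_fixture", {
    sim <- simulate_cohort(default_config(1L), 20000)
    model <- fit_generator(sim$cohort, seed = 2L)
    syn <- sample_synthetic(model, 20000, seed = 3L)
    list(sim = sim, cohort = sim$cohort, model = model, syn = syn)
  })
}

# desk-scale study: original n = 1606, split, fit, sample
study_fixture <- function() {
  cached("study_fixture", {
    sim <- simulate_cohort(default_config(7L), 1606)
    original <- sim$cohort
    original$label <- "original"
    parts <- split_train_test(original, 0.8, seed = 8L)
    model <- fit_generator(parts$train, seed = 9L)
    syn <- sample_synthetic(model, 1606, seed = 10L)
    list(original = original, parts = parts, model = model, syn = syn)
  })
}

# minimal schema with endpoints for small hand-built cohorts
mini_schema <- function(extra = list()) {
  specs <- c(extra, list(
    variable_spec("cr", "binary"),
    variable_spec("efs_time", "time", units = "months",
                  pair = "efs_event"),
    variable_spec("efs_event", "event_indicator"),
    variable_spec("os_time", "time", units = "months", pair = "os_event"),
    variable_spec("os_event", "event_indicator")))
  cohort_schema(specs, cr = "cr", efs = c("efs_time", "efs_event"),
                os = c("os_time", "os_event"))
}

# exponential-survival cohort on the minimal schema with one binary group
mini_surv_cohort <- function(n, log_hr = 0, p_group = 0.5, rate = 0.05,
                             seed = 1L, label = "fixture") {
  set.seed(seed)
  g <- stats::rbinom(n, 1, p_group)
  t_ev <- stats::rexp(n, rate = rate * exp(log_hr * g))
  cens <- stats::runif(n, 24, 120)
  os_t <- round(pmin(t_ev, cens), 1)
  os_e <- as.integer(t_ev <= cens)
  delta <- pmin(stats::rgamma(n, 1.2, scale = 6), os_t)
  efs_t <- round(pmax(0, os_t - delta), 1)
  cohort_table(data.frame(grp = as.character(g),
                          cr = as.character(stats::rbinom(n, 1, 0.7)),
                          efs_time = efs_t,
                          efs_event = as.character(os_e),
                          os_time = os_t,
                          os_event = as.character(os_e),
                          stringsAsFactors = FALSE),
               mini_schema(list(variable_spec("grp", "binary"))),
               label = label)
}

# independent product-limit (Kaplan-Meier) oracle used against km_estimate
brute_km <- function(times, events) {
  ut <- sort(unique(times))
  s <- 1
  out_t <- numeric(0); out_s <- numeric(0)
  for (tt in ut) {
    at_risk <- sum(times >= tt)
    d <- sum(times == tt & events == 1)
    if (at_risk > 0) s <- s * (1 - d / at_risk)
    out_t <- c(out_t, tt); out_s <- c(out_s, s)
  }
  list(time = out_t, surv = out_s)
}

expect_valid_cohort <- function(cohort) {
  expect_s3_class(cohort, "cohort_table")
  rebuilt <- cohort_table(cohort$data, cohort$schema, cohort$label)
  expect_identical(rebuilt$data, cohort$data)
}
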