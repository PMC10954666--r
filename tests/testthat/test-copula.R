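test_that("EFS reconstruction clips into [0, OS]", {
  expect_equal(reconstruct_efs(10, 3), 7)
  expect_equal(reconstruct_efs(5, 7), 0)
  expect_equal(reconstruct_efs(12, -1), 12)   # negative difference clipped
  os <- runif(100, 0, 50); dl <- runif(100, -5, 60)
  efs <- reconstruct_efs(os, dl)
  expect_true(all(efs >= 0 & efs <= os))
})

test_that("nearest_correlation repairs, rescales and is idempotent", {
  expect_equal(nearest_correlation(diag(3)), diag(3))
  m <- matrix(c(1, 1.2, 1.2, 1), 2)
  out <- nearest_correlation(m)
  expect_true(abs(out[1, 2]) < 1)
  expect_gt(out[1, 2], 0.99)    # eigen-clip by hand: (1.1-e)/(1.1+e) -> 1
  ev <- eigen(out, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > 0)
  pd <- matrix(c(1, 0.4, 0.1, 0.4, 1, -0.2, 0.1, -0.2, 1), 3)
  expect_equal(nearest_correlation(pd), pd, tolerance = 1e-10)
  expect_error(nearest_correlation(matrix(1, 2, 3)), "square")
})

test_that("repaired matrix is at least as close as any coarse-grid
           diagonal-preserving candidate", {
  m <- matrix(c(1, 0.9, -0.3, 0.9, 1, 0.9, -0.3, 0.9, 1), 3)
  out <- nearest_correlation(m)
  d_out <- sqrt(sum((out - m)^2))
  g <- seq(-0.95, 0.95, by = 0.05)
  best <- Inf
  for (a in g) for (b in g) for (cc in g) {
    cand <- matrix(c(1, a, b, a, 1, cc, b, cc, 1), 3)
    if (min(eigen(cand, symmetric = TRUE,
                  only.values = TRUE)$values) > 0) {
      d <- sqrt(sum((cand - m)^2))
      if (d < best) best <- d
    }
  }
  expect_lte(d_out, best)
})

test_that("fitting is deterministic and recovers independence", {
  co <- study_fixture()$parts$train
  m1 <- fit_generator(co, seed = 5L)
  m2 <- fit_generator(co, seed = 5L)
  m1$fit_meta$timestamp <- m2$fit_meta$timestamp <- NULL
  expect_equal(m1, m2)

  # independent fixture with informative (non-rare) binaries: fitted
  # off-diagonal latent correlations stay near zero at n = 20000
  cfg <- default_config(21L)
  cfg$latent_corr <- diag(nrow(cfg$latent_corr))
  dimnames(cfg$latent_corr) <- dimnames(default_config(21L)$latent_corr)
  common <- names(which(cfg$alteration_freqs >= 0.2))
  sim <- simulate_cohort(cfg, 20000)
  model <- fit_generator(sim$cohort, seed = 22L)
  block <- model$latent_corr[c("age", "wbc", "hb", "plt", common),
                             c("age", "wbc", "hb", "plt", common)]
  off <- block[upper.tri(block)]
  expect_lt(max(abs(off)), 0.05)
})

test_that("two perfectly correlated binaries hit the tetrachoric limit", {
  set.seed(6)
  n <- 500
  b <- as.character(rbinom(n, 1, 0.5))
  co <- cohort_table(
    data.frame(b1 = b, b2 = b, cr = as.character(rbinom(n, 1, 0.7)),
               efs_time = round(runif(n, 1, 10), 1), efs_event = "1",
               os_time = round(runif(n, 10, 20), 1), os_event = "1",
               stringsAsFactors = FALSE),
    mini_schema(list(variable_spec("b1", "binary"),
                     variable_spec("b2", "binary"))))
  model <- fit_generator(co, seed = 1L)
  expect_gte(model$latent_corr["b1", "b2"], 0.95)
})

test_that("sampling reproduces size, support, frequencies and missingness", {
  bf <- big_fixture()
  syn <- bf$syn
  expect_equal(syn$n, 20000)
  expect_valid_cohort(syn)

  # EFS <= OS in every sampled row (the motivating invariant)
  both <- !is.na(syn$data$efs_time) & !is.na(syn$data$os_time)
  expect_true(all(syn$data$efs_time[both] <= syn$data$os_time[both]))

  # alteration frequencies track the training cohort
  for (a in c("NPM1", "DNMT3A", "FLT3_ITD", "TP53", "normal_karyotype")) {
    tr <- mean(bf$cohort$data[[a]] == "1", na.rm = TRUE)
    sy <- mean(syn$data[[a]] == "1", na.rm = TRUE)
    expect_lt(abs(tr - sy), 0.015, label = a)
  }

  # missingness rates match training within MC tolerance
  for (v in c("hb", "plt", "extramedullary", "cr")) {
    tr <- mean(is.na(bf$cohort$data[[v]]))
    sy <- mean(is.na(syn$data[[v]]))
    expect_lt(abs(tr - sy), 0.01, label = v)
  }

  # continuous support bounded by training range; KS distance small
  for (v in c("age", "wbc", "hb", "plt")) {
    tr <- bf$cohort$data[[v]]; sy <- syn$data[[v]]
    expect_gte(min(sy, na.rm = TRUE), min(tr, na.rm = TRUE))
    expect_lte(max(sy, na.rm = TRUE), max(tr, na.rm = TRUE))
    ks <- suppressWarnings(stats::ks.test(tr, sy)$statistic)
    expect_lt(unname(ks), 0.02, label = v)
  }

  # determinism
  s2 <- sample_synthetic(bf$model, 200, seed = 77L)
  s3 <- sample_synthetic(bf$model, 200, seed = 77L)
  expect_identical(s2$data, s3$data)
  expect_error(sample_synthetic(bf$model, 0), "n must be")
})

test_that("generator serialization round-trips through JSON", {
  model <- study_fixture()$model
  path <- withr::local_tempfile(fileext = ".json")
  write_generator(model, path)
  back <- read_generator(path)
  s1 <- sample_synthetic(model, 100, seed = 31L)
  s2 <- sample_synthetic(back, 100, seed = 31L)
  expect_equal(s1$data, s2$data, tolerance = 1e-8)
})

test_that("random-search tuning is seeded, prefix-stable and sane", {
  sf <- study_fixture()
  small_train <- cohort_table(sf$parts$train$data[1:400, ],
                              sf$parts$train$schema, "train")
  holdout <- cohort_table(sf$parts$test$data[1:200, ],
                          sf$parts$test$schema, "holdout")
  t1 <- tune_generator(small_train, holdout, budget = 1, seed = 3L)
  expect_equal(nrow(t1$trace), 1)
  expect_equal(t1$best_objective, t1$trace$objective[1])

  t2 <- tune_generator(small_train, holdout, budget = 3, seed = 3L)
  expect_equal(t1$trace$objective[1], t2$trace$objective[1])
  expect_gte(t2$best_objective, t1$best_objective)
  expect_equal(t2$best_objective, max(t2$trace$objective))

  # a generator trained on the distribution beats a label-permuted one
  model <- fit_generator(small_train, seed = 4L)
  syn_good <- sample_synthetic(model, holdout$n, seed = 5L)
  perm <- syn_good
  set.seed(6)
  perm$data$os_time <- sample(perm$data$os_time)
  perm$data$efs_time <- round(pmin(perm$data$efs_time, perm$data$os_time), 1)
  good <- synthaml:::tuning_objective(holdout, syn_good)
  bad <- synthaml:::tuning_objective(holdout, perm)
  expect_gt(good, bad)
})
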