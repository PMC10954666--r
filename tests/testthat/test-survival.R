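test_that("product-limit estimator matches hand and brute-force values", {
  km <- km_estimate(1:5, rep(1, 5))
  expect_equal(km$survival, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km_median_iqr(km)[["median"]], 3)

  all_cens <- km_estimate(c(3, 6, 9), c(0, 0, 0))
  expect_true(all(all_cens$survival == 1))
  expect_true(is.na(km_median_iqr(all_cens)[["median"]]))

  single <- km_estimate(1, 1)
  expect_equal(single$survival, 0)

  # exhaustive brute-force oracle on random censored inputs with ties
  for (case in 1:20) {
    set.seed(case)
    n <- sample(5:200, 1)
    times <- round(rexp(n, 0.1), sample(0:1, 1))
    events <- rbinom(n, 1, 0.6)
    got <- km_estimate(times, events)
    ref <- brute_km(times, events)
    expect_equal(got$event_times, ref$time, info = case)
    expect_equal(got$survival, ref$surv, info = case)
  }
})

test_that("KM quantiles use the first-crossing convention", {
  # plateau above 0.5: median undefined
  km <- km_estimate(c(1, 2, rep(10, 8)), c(1, 1, rep(0, 8)))
  expect_true(is.na(km_median_iqr(km)[["median"]]))
  q <- km_median_iqr(km_estimate(1:5, rep(1, 5)))
  expect_equal(q[["q1"]], 2)   # first time S <= 0.75
  expect_equal(q[["q3"]], 4)   # first time S <= 0.25
})

test_that("reverse KM follow-up flips the event indicator", {
  expect_equal(reverse_km_followup(rep(12, 10),
                                   rep(0, 10))[["median"]], 12)
  expect_warning(r <- reverse_km_followup(1:10, rep(1, 10)), "censored")
  expect_true(is.na(r[["median"]]))

  # against the flipped-indicator product-limit oracle on a fixture with
  # administrative censoring
  co <- study_fixture()$original$data
  times <- co$os_time; events <- as.integer(co$os_event == "1")
  got <- reverse_km_followup(times, events)[["median"]]
  ref <- brute_km(times, 1 - events)
  expect_equal(got, ref$time[min(which(ref$surv <= 0.5))])
})

test_that("log-rank test matches a hand-computed toy and has power", {
  ga <- list(times = c(1, 3, 5), events = c(1, 1, 1))
  expect_equal(logrank_test(ga, ga)$statistic, 0, tolerance = 1e-10)
  expect_equal(logrank_test(ga, ga)$p, 1, tolerance = 1e-10)

  # hand computation: A events at 1 and 3; B events at 2 and 4
  ga <- list(times = c(1, 3), events = c(1, 1))
  gb <- list(times = c(2, 4), events = c(1, 1))
  # risk sets: t=1 (2A,2B) dA=1; t=2 (1A,2B) dB=1; t=3 (1A,1B) dA=1;
  # t=4 (0A,1B) dB=1
  ea <- 1 * 2/4 + 1 * 1/3 + 1 * 1/2 + 1 * 0
  va <- (2 * 2)/(4^2) + (1 * 2)/(3^2) + (1 * 1)/(2^2)
  stat_hand <- (2 - ea)^2 / va
  got <- logrank_test(ga, gb)
  expect_equal(got$statistic, stat_hand, tolerance = 1e-8)

  set.seed(50)
  n <- 2500
  a <- list(times = rexp(n, 0.05), events = rep(1, n))
  b <- list(times = rexp(n, 0.10), events = rep(1, n))
  expect_lt(logrank_test(a, b)$p, 0.001)
})

test_that("Cox fits are null-calibrated and recover planted effects", {
  set.seed(51)
  n <- 20000
  x <- rbinom(n, 1, 0.3)
  t0 <- rexp(n, 0.05)
  expect_true(cox_hr(t0, rep(1, n), x)$point > 0.9 &&
                cox_hr(t0, rep(1, n), x)$point < 1.1)

  t1 <- rexp(n, 0.05 * exp(0.7 * x))
  cens <- runif(n, 10, 60)
  est <- cox_hr(pmin(t1, cens), as.integer(t1 <= cens), x)
  expect_lt(abs(log(est$point) - 0.7), 0.1)
  expect_true(est$ci_low <= est$point && est$point <= est$ci_high)

  expect_error(cox_hr(t0, rep(1, n), rep(1, n)), "constant")
})

test_that("Cox and log-rank agree in direction and significance", {
  co <- mini_surv_cohort(2000, log_hr = 0.5, seed = 52)
  g <- co$data$grp == "1"
  est <- cox_hr(co$data$os_time, as.integer(co$data$os_event == "1"),
                co$data$grp)
  lr <- logrank_test(
    list(times = co$data$os_time[!g],
         events = as.integer(co$data$os_event == "1")[!g]),
    list(times = co$data$os_time[g],
         events = as.integer(co$data$os_event == "1")[g]))
  expect_gt(est$point, 1)
  expect_lt(est$p, 0.05)
  expect_lt(lr$p, 0.05)
})

test_that("odds of response and its Wald interval match printed values", {
  est <- logistic_odds(1135, 471)
  expect_equal(round(est$point, 2), 2.41)
  expect_equal(round(est$ci_low, 2), 2.16)
  expect_equal(round(est$ci_high, 2), 2.68)
  expect_equal(round(logistic_odds(1184, 422)$point, 2), 2.81)
  expect_equal(logistic_odds(10, 10)$point, 1.0)

  z <- logistic_odds(5, 0)
  expect_true(is.na(z$ci_low))
  h <- logistic_odds(5, 0, haldane = TRUE)
  expect_true(is.finite(h$ci_low))
})

test_that("Wald interval for the odds has near-nominal coverage", {
  set.seed(53)
  n <- 1606; p <- 0.707
  true_odds <- p / (1 - p)
  k <- rbinom(2000, n, p)
  lo <- exp(log(k / (n - k)) - 1.96 * sqrt(1 / k + 1 / (n - k)))
  hi <- exp(log(k / (n - k)) + 1.96 * sqrt(1 / k + 1 / (n - k)))
  cover <- mean(lo <= true_odds & true_odds <= hi)
  expect_lt(abs(cover - 0.95), 0.015)
  # spot-check the vectorized oracle against the implementation
  est <- logistic_odds(k[1], n - k[1])
  expect_equal(est$ci_low, lo[1]); expect_equal(est$ci_high, hi[1])
})

test_that("logistic odds ratio equals the 2x2 cross-product with Wald CI", {
  set.seed(54)
  n <- 800
  x <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x))
  est <- logistic_or(y, x)
  a <- sum(y == 1 & x == 1); b <- sum(y == 0 & x == 1)
  cc <- sum(y == 1 & x == 0); d <- sum(y == 0 & x == 0)
  or_hand <- (a * d) / (b * cc)
  se_hand <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  expect_equal(est$point, or_hand, tolerance = 1e-6)
  expect_equal(est$ci_high, exp(log(or_hand) + 1.96 * se_hand),
               tolerance = 1e-4)
})

test_that("the Shapiro gate selects the right two-sample test", {
  set.seed(55)
  a <- rnorm(500); b <- rnorm(500, 1)
  res <- compare_continuous(a, b)
  expect_equal(res$test, "t")
  expect_lt(res$p, 1e-10)

  same <- rnorm(100)
  expect_gte(compare_continuous(same, same)$p, 0.99)

  la <- rlnorm(500); lb <- rlnorm(500)
  expect_equal(compare_continuous(la, lb)$test, "wilcoxon")
})

test_that("Fisher's exact test reproduces published sex-table p-values", {
  expect_equal(round(fisher_exact(matrix(c(768, 838, 703, 903), 2)), 3),
               0.023)
  expect_equal(round(fisher_exact(matrix(c(768, 838, 781, 825), 2)), 3),
               0.672)
  expect_equal(fisher_exact(matrix(c(10, 5, 10, 5), 2)), 1.0)
  expect_warning(p0 <- fisher_exact(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_equal(p0, 1)

  # symmetry under row and column swaps
  for (i in 1:10) {
    set.seed(i)
    m <- matrix(rpois(4, 20), 2)
    p <- fisher_exact(m)
    expect_equal(fisher_exact(m[2:1, ]), p)
    expect_equal(fisher_exact(m[, 2:1]), p)
    expect_equal(fisher_exact(t(m)), p)
  }
})
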