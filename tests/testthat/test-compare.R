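test_that("baseline table is null on self-comparison and finds a shift", {
  sf <- study_fixture()
  base_vars <- c("age", "sex", "wbc", "hb", "plt")
  tab <- baseline_table(sf$original, list(sf$original),
                        variables = base_vars)
  expect_true(all(tab$p > 0.99))
  expect_false(any(tab$significant))

  shifted <- sf$original
  shifted$data$hb <- shifted$data$hb + 2 * sd(shifted$data$hb,
                                              na.rm = TRUE)
  tab2 <- baseline_table(sf$original, list(shifted),
                         variables = base_vars)
  hb_row <- tab2[tab2$variable == "hb", ]
  expect_lt(hb_row$p, 1e-10)
  expect_true(hb_row$significant)
  expect_equal(tab2$p[which.min(tab2$p)], hb_row$p)
})

test_that("categorical baseline rows reproduce the published sex test", {
  sch <- cohort_schema(list(variable_spec("sex", "categorical",
                                          categories = c("female",
                                                         "male"))))
  orig <- cohort_table(
    data.frame(sex = rep(c("female", "male"), c(768, 838))), sch)
  ctab <- cohort_table(
    data.frame(sex = rep(c("female", "male"), c(703, 903))), sch)
  nflw <- cohort_table(
    data.frame(sex = rep(c("female", "male"), c(781, 825))), sch)
  tab <- baseline_table(orig, list(ctabgan = ctab, nflow = nflw))
  p_ct <- tab$p[tab$cohort == "ctabgan" & tab$level == "female"]
  p_nf <- tab$p[tab$cohort == "nflow" & tab$level == "female"]
  expect_equal(round(p_ct, 3), 0.023)
  expect_equal(round(p_nf, 3), 0.672)
  expect_true(tab$significant[tab$cohort == "ctabgan"][1])
})

test_that("outcome table: self-comparison is null, planted HR recovered", {
  co <- mini_surv_cohort(800, log_hr = 0, seed = 70)
  tab <- outcome_table(co, list(co))
  expect_equal(tab$os_hr[2], 1.0, tolerance = 1e-6)
  expect_gt(tab$os_logrank_p[2], 0.999)
  expect_equal(tab$cr_odds[1],
               sum(co$data$cr == "1") / sum(co$data$cr == "0"))

  # synthetic cohort with true hazard 0.74x the original
  orig <- mini_surv_cohort(20000, log_hr = 0, rate = 0.05, seed = 71)
  syn <- mini_surv_cohort(20000, log_hr = 0, rate = 0.05 * 0.74,
                          seed = 72)
  tab2 <- outcome_table(orig, list(syn))
  expect_lt(abs(tab2$os_hr[2] - 0.74), 0.05)
})

test_that("alteration frequency table flags only planted deviations", {
  sf <- study_fixture()
  tab <- alteration_frequencies(sf$original, list(sf$original))
  expect_true(all(tab$fisher_p > 0.999))

  doubled <- sf$original
  set.seed(73)
  idx <- which(doubled$data$TET2 == "0")
  flip <- sample(idx, round(0.1 * sf$original$n))
  doubled$data$TET2[flip] <- "1"
  tab2 <- alteration_frequencies(sf$original, list(doubled))
  expect_true(tab2$highly_significant[tab2$alteration == "TET2"])
  expect_lt(mean(tab2$highly_significant), 0.1)
})

test_that("co-occurrence differences match brute-force counting", {
  sf <- study_fixture()
  d <- cooccurrence_diff(sf$original, sf$original)
  expect_true(all(d == 0))
  expect_true(all(d >= -100 & d <= 100))

  d2 <- cooccurrence_diff(sf$original, sf$syn)
  expect_true(all(d2 >= -100 & d2 <= 100))
  expect_equal(d2, t(d2))
  eps <- 1 / sf$original$n
  for (pair in list(c("NPM1", "FLT3_ITD"), c("TP53", "TET2"))) {
    po <- mean(sf$original$data[[pair[1]]] == "1" &
                 sf$original$data[[pair[2]]] == "1", na.rm = FALSE)
    po <- sum(!is.na(sf$original$data[[pair[1]]]) &
                !is.na(sf$original$data[[pair[2]]]) &
                sf$original$data[[pair[1]]] == "1" &
                sf$original$data[[pair[2]]] == "1") / sf$original$n
    ps <- sum(!is.na(sf$syn$data[[pair[1]]]) &
                !is.na(sf$syn$data[[pair[2]]]) &
                sf$syn$data[[pair[1]]] == "1" &
                sf$syn$data[[pair[2]]] == "1") / sf$syn$n
    ref <- max(-100, min(100, 100 * (ps - po) / max(po, eps)))
    expect_equal(unname(d2[pair[1], pair[2]]), ref, info = pair[1])
  }

  # a pair present in the original but absent in the synthetic clamps
  wiped <- sf$syn
  wiped$data$NPM1[wiped$data$FLT3_ITD == "1" &
                    !is.na(wiped$data$FLT3_ITD)] <- "0"
  d3 <- cooccurrence_diff(sf$original, wiped)
  expect_equal(unname(d3["NPM1", "FLT3_ITD"]), -100)
})

test_that("concordance classification is a pure function of four flags", {
  truth <- function(dr, ds, sr, ss) {
    if (dr != ds && (sr || ss)) return("inverse")
    if (sr && ss) return("concordant_significant")
    if (!sr && !ss) return("concordant_nonsignificant")
    "significance_discordant"
  }
  for (dr in c(-1, 1)) for (ds in c(-1, 1))
    for (sr in c(TRUE, FALSE)) for (ss in c(TRUE, FALSE))
      expect_equal(synthaml:::classify_concordance(dr, ds, sr, ss),
                   truth(dr, ds, sr, ss),
                   info = paste(dr, ds, sr, ss))
})

test_that("concordance matrix counts classes and inverse cells", {
  panel <- data.frame(marker = c("a", "b", "c"),
                      endpoint = c("OS", "OS", "CR"),
                      point = c(2, 0.5, 1.5),
                      p = c(0.001, 0.2, 0.01))
  self <- concordance_matrix(panel, panel)
  expect_equal(self$n_inverse, 0)
  expect_true(all(self$cells$class %in% c("concordant_significant",
                                          "concordant_nonsignificant")))

  flipped <- panel
  flipped$point[1] <- 1 / panel$point[1]
  one <- concordance_matrix(panel, flipped)
  expect_equal(one$n_inverse, 1)
  expect_equal(one$cells$class[one$cells$marker == "a"], "inverse")

  bad <- panel; bad$marker[1] <- "zz"
  expect_error(concordance_matrix(panel, bad), "mismatched")
})

test_that("univariable panel recovers directions with calibrated CIs", {
  bf <- big_fixture()
  panel <- cached("panel_real", univariable_panel(bf$cohort))
  age_os <- panel[panel$marker == "age" & panel$endpoint == "OS", ]
  expect_gt(age_os$point, 1)           # older age is adverse
  expect_lt(age_os$p, 0.001)
  tp53_cr <- panel[panel$marker == "TP53" & panel$endpoint == "CR", ]
  expect_lt(tp53_cr$point, 1)          # TP53 reduces remission odds
  expect_error(univariable_panel(bf$cohort, markers = c("nope")), "nope")

  # null-marker CI coverage over replicates
  set.seed(74)
  hits <- 0; reps <- 200
  for (i in seq_len(reps)) {
    x <- rbinom(400, 1, 0.3)
    y <- rbinom(400, 1, 0.6)
    est <- logistic_or(y, x)
    if (est$ci_low <= 1 && 1 <= est$ci_high) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.93)
})

test_that("generator-sampled cohorts show no inverse effects at scale", {
  bf <- big_fixture()
  panel_real <- cached("panel_real", univariable_panel(bf$cohort))
  panel_syn <- cached("panel_syn", univariable_panel(bf$syn))
  cc <- concordance_matrix(panel_real, panel_syn)
  expect_equal(cc$n_inverse, 0)
  expect_gt(sum(cc$cells$class == "concordant_significant"), 24)
})
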