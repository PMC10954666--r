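# small helper: binned cohort straight from a label matrix
label_cohort <- function(M, label = "x") {
  M <- as.matrix(M)
  specs <- lapply(colnames(M), function(nm)
    variable_spec(nm, "categorical", categories = sort(unique(c(M))),
                  missing_allowed = TRUE))
  structure(list(data = as.data.frame(M, stringsAsFactors = FALSE),
                 schema = cohort_schema(specs), label = label,
                 n = nrow(M), n_bins = 10, bin_edges = list()),
            class = "binned_cohort")
}

test_that("Hamming distance counts differing labels with na == na", {
  a <- c(x = "1", y = "na", z = "b03")
  expect_equal(hamming_distance(a, a), 0)
  b <- a; b[["x"]] <- "0"; b[["z"]] <- "b04"
  expect_equal(hamming_distance(a, b), 2)
  expect_equal(hamming_distance(c("na", "1"), c("na", "2")), 1)
  expect_error(hamming_distance(a, a[1:2]), "schema")
})

test_that("training partition yields equal test-sized disjoint subsets", {
  tr <- bin_numeric(study_fixture()$parts$train)
  subs <- partition_training(tr, test_n = 321, k = 4, seed = 2L)
  expect_equal(vapply(subs, `[[`, numeric(1), "n"), rep(321, 4))
  expect_equal(attr(subs, "n_surplus"), 0)
  # the paper-style arithmetic: 1284 training rows, 322 test rows
  subs2 <- partition_training(tr, test_n = 322, k = 4, seed = 2L)
  expect_equal(vapply(subs2, `[[`, numeric(1), "n"), rep(321, 4))

  again <- partition_training(tr, test_n = 321, k = 4, seed = 2L)
  expect_identical(subs[[2]]$data, again[[2]]$data)
  ids <- unlist(lapply(subs, function(s) rownames(s$data)))
  expect_equal(anyDuplicated(ids), 0)
  expect_error(partition_training(tr, test_n = 500, k = 4), "too small")
})

test_that("minimum-distance statistics match brute force", {
  q <- label_cohort(matrix(c("0", "0", "1", "1"), 2, byrow = TRUE,
                           dimnames = list(NULL, c("a", "b"))))
  r <- label_cohort(matrix(c("0", "0", "0", "1"), 2, byrow = TRUE,
                           dimnames = list(NULL, c("a", "b"))))
  got <- avg_min_distance(q, r)
  expect_equal(got$minima, c(0, 1))
  expect_equal(got$mean, 0.5)
  expect_equal(got$median, 0.5)

  # query contained in the reference: all-zero minima
  sub <- label_cohort(r$data[1, , drop = FALSE])
  expect_equal(avg_min_distance(sub, r)$mean, 0)

  # randomized brute-force double-loop oracle
  set.seed(60)
  for (case in 1:3) {
    M1 <- matrix(sample(c("0", "1", "na"), 40 * 6, TRUE), 40,
                 dimnames = list(NULL, letters[1:6]))
    M2 <- matrix(sample(c("0", "1", "na"), 55 * 6, TRUE), 55,
                 dimnames = list(NULL, letters[1:6]))
    got <- avg_min_distance(label_cohort(M1), label_cohort(M2))
    ref <- apply(M1, 1, function(row)
      min(apply(M2, 1, function(r2) sum(row != r2))))
    expect_equal(got$minima, unname(ref))
    expect_equal(got$mean, round(mean(ref), 4))
    expect_equal(got$median, median(ref))
  }

  # row-order invariance
  got2 <- avg_min_distance(label_cohort(M1[sample(40), ]),
                           label_cohort(M2[sample(55), ]))
  expect_equal(sort(got2$minima), sort(unname(ref)))
  expect_equal(got2$mean, got$mean)
})

test_that("leakage coefficient reproduces the published arithmetic", {
  expect_equal(round(leakage_coefficient(8.8587, 8.7034), 4), 0.0178)
  expect_equal(round(leakage_coefficient(9.4117, 9.3474), 4), 0.0069)
  expect_equal(leakage_coefficient(5, 5), 0)
})

test_that("exact-match counting uses raw values with missing == missing", {
  co <- study_fixture()$original
  small <- cohort_table(co$data[1:50, ], co$schema, "small")
  expect_equal(count_exact_matches(small, co), 50)
  syn <- study_fixture()$syn
  planted <- syn
  planted$data[7, ] <- co$data[123, ]
  expect_equal(count_exact_matches(planted, co) -
                 count_exact_matches(syn, co), 1)
})

test_that("copied training rows trigger the breach path", {
  sf <- study_fixture()
  train <- sf$parts$train; test <- sf$parts$test
  copies <- cohort_table(train$data[1:322, ], train$schema, "copies")
  rep <- privacy_report(copies, train, test, seed = 3L)
  expect_true(rep$breach_flag)
  expect_gt(rep$leakage_coefficient, 0.05)
  expect_equal(rep$exact_matches, 322)

  # degenerate zero-distance reference: coefficient undefined, flagged
  cb <- bin_numeric(copies, edges_from = train)
  tb <- bin_numeric(test, edges_from = train)
  ref0 <- cb                       # distinct object containing every row
  ref0$data <- rbind(cb$data, cb$data)
  ref0$n <- nrow(ref0$data)
  expect_warning(z <- privacy_leakage_coefficient(cb, list(ref0), tb),
                 "coincide")
  expect_true(z$breach_flag)
  expect_true(is.na(z$leakage_coefficient))
})

test_that("independently generated synthetic data passes the threshold", {
  rep <- cached("privacy_clean", {
    sf <- study_fixture()
    privacy_report(sf$syn, sf$parts$train, sf$parts$test, seed = 3L)
  })
  expect_lt(abs(rep$leakage_coefficient), 0.05)
  expect_false(rep$breach_flag)
  expect_equal(rep$exact_matches, 0)
  expect_equal(rep$k_subsets, 4)
  expect_gt(rep$avg_min_dist_syn_train, 0)

  # coefficient is invariant to category relabeling
  sf <- study_fixture()
  relab <- function(co) {
    co$data$sex <- c(female = "F", male = "M")[co$data$sex]
    co$schema$specs$sex$categories <- c("F", "M", "na")
    co
  }
  rep2 <- privacy_report(relab(sf$syn), relab(sf$parts$train),
                         relab(sf$parts$test), seed = 3L)
  expect_equal(rep2$leakage_coefficient, rep$leakage_coefficient)
})
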