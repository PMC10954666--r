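# Distance-based privacy assessment: exact-match counting, minimum Hamming
# distances on the binned (fully categorical) feature space, and the
# privacy leakage coefficient
#   (syn -> test) / (syn -> train) - 1
# where values above 0.05 flag a potential privacy breach (the synthetic
# data sits substantially closer to its training records than to unseen
# test records).

#' Hamming distance between two binned records
#'
#' Counts positions with differing labels; the missing label `"na"` equals
#' `"na"`.
#'
#' @param a,b Character vectors of category labels over the same variables.
#' @return Non-negative integer.
#' @export
hamming_distance <- function(a, b) {
  if (length(a) != length(b) ||
      (!is.null(names(a)) && !is.null(names(b)) &&
       !identical(names(a), names(b))))
    stop("records must share one schema")
  sum(as.character(a) != as.character(b))
}

# integer-code both binned tables over a shared label space
binned_codes <- function(query, reference) {
  nms <- schema_names(query$schema)
  if (!identical(nms, schema_names(reference$schema)))
    stop("binned cohorts have different schemas")
  code <- function(qc, rc) {
    lev <- sort(unique(c(qc, rc)))
    list(q = match(qc, lev), r = match(rc, lev))
  }
  q <- matrix(0L, query$n, length(nms))
  r <- matrix(0L, reference$n, length(nms))
  for (j in seq_along(nms)) {
    cc <- code(query$data[[nms[j]]], reference$data[[nms[j]]])
    q[, j] <- cc$q; r[, j] <- cc$r
  }
  list(q = q, r = r)
}

# per-query minimum Hamming distance via column-wise accumulation
min_hamming <- function(query, reference, exclude_self = FALSE) {
  cc <- binned_codes(query, reference)
  nq <- nrow(cc$q); nr <- nrow(cc$r)
  if (nr == 0) stop("empty reference")
  D <- matrix(0L, nq, nr)
  for (j in seq_len(ncol(cc$q)))
    D <- D + outer(cc$q[, j], cc$r[, j], "!=")
  if (exclude_self) {
    if (nq != nr) stop("self-exclusion requires equal row sets")
    diag(D) <- NA_integer_
  }
  apply(D, 1, min, na.rm = TRUE)
}

#' Average and median minimum Hamming distance
#'
#' For each query record, the minimum Hamming distance to any reference
#' record; self-pairs are excluded when both arguments are the same binned
#' table.
#'
#' @param query,reference `binned_cohort`s (see [bin_numeric()]) on one
#'   schema and label space.
#' @return List with `mean` (rounded to 4 decimals), `median`, and the
#'   per-query `minima`.
#' @export
avg_min_distance <- function(query, reference) {
  self <- identical(query$data, reference$data)
  m <- min_hamming(query, reference, exclude_self = self)
  list(mean = round(mean(m), 4), median = stats::median(m), minima = m)
}

#' Partition training data into equally sized reference subsets
#'
#' Seeded shuffle into `k` disjoint subsets of `test_n` rows each (matching
#' the test-set size for balanced comparisons); surplus rows are left
#' unassigned and reported.
#'
#' @param train A [cohort_table()] or `binned_cohort`.
#' @param test_n Target subset size.
#' @param k Number of subsets.
#' @param seed Integer seed.
#' @return List of `k` subsets (same class as input); attribute
#'   `n_surplus` counts unassigned rows.
#' @export
partition_training <- function(train, test_n, k = 4, seed = 1L) {
  size <- min(test_n, floor(train$n / k))
  if (size < 1)
    stop("training data too small for ", k, " subsets")
  if (k * test_n > train$n + k)
    stop("training data too small for ", k, " subsets of ~", test_n)
  restore <- local_rng(seed)
  on.exit(restore())
  idx <- sample.int(train$n)
  subsets <- lapply(seq_len(k), function(i) {
    rows <- sort(idx[seq.int((i - 1) * size + 1, i * size)])
    out <- train
    out$data <- train$data[rows, , drop = FALSE]
    out$n <- length(rows)
    out$label <- paste0(train$label, ":subset", i)
    out
  })
  attr(subsets, "n_surplus") <- train$n - k * size
  subsets
}

#' Privacy leakage coefficient from average minimum distances
#'
#' `syn_to_test / syn_to_train - 1`: near zero when the synthetic data
#' sits as far from its training records as from unseen test records.
#'
#' @param syn_to_test,syn_to_train Average minimum Hamming distances.
#' @return The coefficient (unrounded).
#' @export
leakage_coefficient <- function(syn_to_test, syn_to_train) {
  if (syn_to_train == 0) stop("syn_to_train distance is zero")
  syn_to_test / syn_to_train - 1
}

#' Privacy leakage coefficient and Hamming-distance report
#'
#' `syn -> train` is the mean over the subset-level average minimum
#' distances; `syn -> test` the average minimum distance to the test set.
#' The coefficient `(syn -> test)/(syn -> train) - 1` is flagged as a
#' potential breach above the 0.05 threshold. Medians are pooled per-query
#' minima.
#'
#' @param syn Synthetic `binned_cohort`.
#' @param train_subsets List of training `binned_cohort` subsets (from
#'   [partition_training()]).
#' @param test Test `binned_cohort`.
#' @param threshold Breach threshold (default 0.05).
#' @return A `privacy_report` list.
#' @export
privacy_leakage_coefficient <- function(syn, train_subsets, test,
                                        threshold = 0.05) {
  if (!length(train_subsets)) stop("need at least one training subset")
  per_subset <- lapply(train_subsets, function(s) avg_min_distance(syn, s))
  d_train <- mean(vapply(per_subset, `[[`, numeric(1), "mean"))
  minima_train <- unlist(lapply(per_subset, `[[`, "minima"))
  to_test <- avg_min_distance(syn, test)
  d_test <- to_test$mean
  if (d_train == 0) {
    warning("synthetic rows coincide with training rows; coefficient ",
            "undefined, breach flagged")
    coef <- NA_real_
    breach <- TRUE
  } else {
    coef <- leakage_coefficient(d_test, d_train)
    breach <- coef > threshold
  }
  structure(list(avg_min_dist_syn_train = round(d_train, 4),
                 avg_min_dist_syn_test = d_test,
                 median_dist_train = stats::median(minima_train),
                 median_dist_test = to_test$median,
                 leakage_coefficient = if (is.na(coef)) coef
                                       else round(coef, 4),
                 threshold = threshold,
                 breach_flag = breach,
                 k_subsets = length(train_subsets)),
            class = "privacy_report")
}

#' Count synthetic rows that exactly match an original row
#'
#' Comparison on raw (un-binned) values with missing-equals-missing.
#'
#' @param syn,original [cohort_table()]s on one schema.
#' @return Number of synthetic rows identical to at least one original row.
#' @export
count_exact_matches <- function(syn, original) {
  check_same_schema(syn, original)
  key <- function(df) {
    cols <- lapply(df, function(v) {
      v <- as.character(v)
      v[is.na(v)] <- "\r.na"
      v
    })
    do.call(paste, c(cols, sep = "\r"))
  }
  sum(key(syn$data) %in% key(original$data))
}

#' End-to-end privacy assessment of a synthetic cohort
#'
#' Bins all cohorts onto the original cohort's deciles (one shared label
#' space), partitions the training part into `k` test-sized subsets, and
#' computes the leakage coefficient, the original-cohort baseline column
#' (test -> train subsets, and train subset 1 -> test), and the exact-match
#' count against the full original cohort.
#'
#' @param syn Synthetic [cohort_table()].
#' @param train,test Original training and test [cohort_table()]s.
#' @param k Number of training subsets.
#' @param seed Partition seed.
#' @param n_bins Bins per numeric variable.
#' @return A `privacy_report` with baseline fields and `exact_matches`.
#' @export
privacy_report <- function(syn, train, test, k = 4, seed = 1L,
                           n_bins = 10) {
  original <- train
  original$data <- rbind(train$data, test$data)
  original$n <- nrow(original$data)
  original$label <- "original"
  syn_b <- bin_numeric(syn, n_bins = n_bins, edges_from = original)
  train_b <- bin_numeric(train, n_bins = n_bins, edges_from = original)
  test_b <- bin_numeric(test, n_bins = n_bins, edges_from = original)
  subsets <- partition_training(train_b, test_n = test$n, k = k, seed = seed)
  rep <- privacy_leakage_coefficient(syn_b, subsets, test_b)
  base_train <- mean(vapply(subsets, function(s)
    avg_min_distance(test_b, s)$mean, numeric(1)))
  base_test <- avg_min_distance(subsets[[1]], test_b)$mean
  rep$baseline_avg_min_train <- round(base_train, 4)
  rep$baseline_avg_min_test <- base_test
  rep$exact_matches <- count_exact_matches(syn, original)
  rep$partition_seed <- seed
  rep
}
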