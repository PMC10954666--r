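# Normalized fidelity scores comparing a synthetic cohort to an original
# one: regularized support coverage (RSC), basic statistical measure (BSM),
# and the log-transformed correlation score (LTCS). All three live in
# [0, 1] and equal 1 when the synthetic cohort is an exact copy.

# labels of one variable in category space, missing as "na"
category_labels <- function(v) {
  v <- as.character(v)
  v[is.na(v)] <- "na"
  v
}

# RSC for one variable: Laplace-smoothed coverage of the real category
# proportions by the synthetic ones
rsc_variable <- function(real_v, syn_v, categories) {
  rl <- category_labels(real_v)
  sl <- category_labels(syn_v)
  cats <- union(categories, union(unique(rl), unique(sl)))
  k <- length(cats)
  cr <- vapply(cats, function(cc) sum(rl == cc), numeric(1))
  cs <- vapply(cats, function(cc) sum(sl == cc), numeric(1))
  pr <- (cr + 1) / (length(rl) + k)
  ps <- (cs + 1) / (length(sl) + k)
  min(max(mean(pmin(1, ps / pr)), 0), 1)
}

#' Regularized support coverage
#'
#' Per-variable coverage of the original category distribution by the
#' synthetic one, with additive (Laplace, lambda = 1) smoothing so absent
#' rare categories degrade the score without zeroing it. Continuous and
#' time variables are first binned onto the original cohort's deciles via
#' [bin_numeric()]; set `include_continuous = FALSE` to score declared
#' categoricals only.
#'
#' @param real,syn [cohort_table()]s sharing one schema.
#' @param include_continuous Include decile-binned numeric variables?
#' @return List with `score` (mean over variables, in `[0, 1]`) and
#'   `per_variable` breakdown.
#' @export
regularized_support_coverage <- function(real, syn,
                                         include_continuous = TRUE) {
  check_same_schema(real, syn)
  rb <- bin_numeric(real, edges_from = real)
  sb <- bin_numeric(syn, edges_from = real)
  per <- numeric(0)
  for (s in real$schema$specs) {
    numeric_kind <- s$kind %in% c("continuous", "time")
    if (numeric_kind && !include_continuous) next
    cats <- if (numeric_kind) sprintf("b%02d", seq_len(rb$n_bins))
            else s$categories
    per[[s$name]] <- rsc_variable(rb$data[[s$name]], sb$data[[s$name]], cats)
  }
  list(score = mean(per), per_variable = per)
}

# BSM for one variable on raw observed values; normalization by the real
# cohort's min-max range
bsm_variable <- function(real_obs, syn_obs) {
  rng <- range(real_obs)
  span <- diff(rng)
  if (span == 0) span <- 1
  nr <- (real_obs - rng[1]) / span
  ns <- (syn_obs - rng[1]) / span
  stats <- c(mean = abs(mean(nr) - mean(ns)),
             median = abs(stats::median(nr) - stats::median(ns)),
             sd = abs(stats::sd(nr) - stats::sd(ns)))
  mean(pmin(pmax(1 - stats, 0), 1))
}

#' Basic statistical measure
#'
#' Compares mean, median and standard deviation per numeric variable after
#' min-max normalization to the original cohort's observed range; each
#' statistic contributes `clip(1 - |real - syn|, 0, 1)`.
#'
#' @param real,syn [cohort_table()]s sharing one schema.
#' @return List with `score` and `per_variable` breakdown. Variables with
#'   fewer than 2 non-missing values in either cohort are excluded with a
#'   warning.
#' @export
basic_statistical_measure <- function(real, syn) {
  check_same_schema(real, syn)
  per <- numeric(0)
  for (s in real$schema$specs) {
    if (!s$kind %in% c("continuous", "time")) next
    r <- real$data[[s$name]]; r <- r[!is.na(r)]
    y <- syn$data[[s$name]];  y <- y[!is.na(y)]
    if (length(r) < 2 || length(y) < 2) {
      warning("variable '", s$name,
              "' has < 2 non-missing values; excluded from BSM")
      next
    }
    per[[s$name]] <- bsm_variable(r, y)
  }
  if (!length(per)) stop("no numeric variables with enough data")
  list(score = mean(per), per_variable = per)
}

check_same_schema <- function(a, b) {
  if (!identical(schema_names(a$schema), schema_names(b$schema)))
    stop("cohorts have different schemas")
  invisible(TRUE)
}

cramers_v <- function(a, b) {
  tab <- table(a, b)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(NA_real_)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  sqrt(as.numeric(chi2) / (sum(tab) * (min(dim(tab)) - 1)))
}

correlation_ratio <- function(x, g) {
  grand <- mean(x)
  ss_tot <- sum((x - grand)^2)
  if (ss_tot == 0) return(NA_real_)
  mg <- tapply(x, g, mean)
  ng <- tapply(x, g, length)
  ss_b <- sum(ng * (mg - grand)^2)
  sqrt(ss_b / ss_tot)
}

# log1p where it is defined for the whole variable, identity otherwise
log_transform <- function(x) {
  if (all(x >= 0, na.rm = TRUE)) log1p(x) else x
}

#' Pairwise association matrix of a cohort
#'
#' Absolute Pearson correlation on log1p-transformed values for numeric
#' pairs, Cramér's V for categorical pairs, and the correlation ratio for
#' mixed pairs; pairwise-complete observations throughout so the missing
#' state never masquerades as a numeric level. Entries with fewer than 3
#' complete pairs are `NA`.
#'
#' @param cohort A [cohort_table()].
#' @return Symmetric matrix in `[0, 1]` with unit diagonal.
#' @export
association_matrix <- function(cohort) {
  kinds <- schema_kinds(cohort$schema)
  nms <- schema_names(cohort$schema)
  if (length(nms) < 2) stop("need at least 2 variables")
  num <- kinds %in% c("continuous", "time")
  d <- length(nms)
  A <- diag(d); dimnames(A) <- list(nms, nms)
  cols <- cohort$data
  for (i in seq_len(d - 1)) for (j in seq((i + 1), d)) {
    x <- cols[[nms[i]]]; y <- cols[[nms[j]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) { A[i, j] <- A[j, i] <- NA_real_; next }
    x <- x[ok]; y <- y[ok]
    val <- if (num[i] && num[j]) {
      r <- suppressWarnings(stats::cor(log_transform(x), log_transform(y)))
      abs(r)
    } else if (!num[i] && !num[j]) {
      cramers_v(x, y)
    } else if (num[i]) {
      correlation_ratio(log_transform(x), y)
    } else {
      correlation_ratio(log_transform(y), x)
    }
    if (!is.finite(val)) val <- NA_real_
    A[i, j] <- A[j, i] <- val
  }
  A
}

#' Log-transformed correlation score
#'
#' `1 - mean(|A_real - A_syn|)` over off-diagonal pairs defined in both
#' association matrices (see [association_matrix()]), clipped to `[0, 1]`.
#'
#' @param real,syn [cohort_table()]s sharing one schema.
#' @return List with `score`, and the two association matrices.
#' @export
log_transformed_correlation_score <- function(real, syn) {
  check_same_schema(real, syn)
  ar <- association_matrix(real)
  as_ <- association_matrix(syn)
  off <- upper.tri(ar)
  dif <- abs(ar - as_)[off]
  dif <- dif[is.finite(dif)]
  if (!length(dif)) stop("no defined association pairs")
  list(score = min(max(1 - mean(dif), 0), 1),
       association_real = ar, association_syn = as_)
}

#' Combined fidelity report
#'
#' @param real,syn [cohort_table()]s sharing one schema.
#' @return List with `rsc`, `bsm`, `ltcs` scores and per-variable details.
#' @export
fidelity_report <- function(real, syn) {
  rsc <- regularized_support_coverage(real, syn)
  bsm <- basic_statistical_measure(real, syn)
  ltcs <- log_transformed_correlation_score(real, syn)
  list(rsc = rsc$score, bsm = bsm$score, ltcs = ltcs$score,
       rsc_per_variable = rsc$per_variable,
       bsm_per_variable = bsm$per_variable)
}
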