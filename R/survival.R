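# Time-to-event and two-sample inference machinery. Standard estimators are
# delegated to the survival package and stats; this module fixes the
# conventions used throughout (Breslow ties, two-sided tests, Wald CIs,
# Shapiro-gated test choice) and the curve/effect containers.

#' Kaplan-Meier product-limit estimate
#'
#' @param times Follow-up times in months (non-negative).
#' @param events Event indicators (1 = event, 0 = censored).
#' @return A `km_curve`: `event_times` (sorted distinct observed times),
#'   `survival` (step values), `at_risk`, `censor_marks`, `n`.
#' @export
km_estimate <- function(times, events) {
  events <- as.integer(events)
  ok <- !is.na(times) & !is.na(events)
  times <- times[ok]; events <- events[ok]
  if (!length(times)) stop("empty input")
  if (any(times < 0)) stop("negative times")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log")
  structure(list(event_times = fit$time, survival = fit$surv,
                 at_risk = fit$n.risk,
                 censor_marks = fit$time[fit$n.censor > 0],
                 n = length(times)),
            class = "km_curve")
}

# step-function evaluation of a km_curve, carried forward flat
km_surv_at <- function(curve, t) {
  idx <- findInterval(t, curve$event_times)
  s <- c(1, curve$survival)[idx + 1L]
  s
}

#' Median and quartiles of a Kaplan-Meier curve
#'
#' The median is the first time at which the curve reaches 0.5 or below;
#' quartiles analogously at 0.75 / 0.25. A quantile the curve never crosses
#' is `NA` (e.g. when survival plateaus above it).
#'
#' @param curve A `km_curve` from [km_estimate()].
#' @return Named numeric vector `c(median, q1, q3)` in months.
#' @export
km_median_iqr <- function(curve) {
  cross <- function(level) {
    i <- which(curve$survival <= level + 1e-12)
    if (!length(i)) NA_real_ else curve$event_times[min(i)]
  }
  c(median = cross(0.5), q1 = cross(0.75), q3 = cross(0.25))
}

#' Median follow-up by the reverse Kaplan-Meier method
#'
#' Flips the event indicator (censorings become the events of interest) and
#' reports the median of that curve with a log-log 95% CI.
#'
#' @inheritParams km_estimate
#' @return Named vector `c(median, ci_low, ci_high)` in months; all `NA`
#'   with a warning when no observation is censored.
#' @export
reverse_km_followup <- function(times, events) {
  events <- as.integer(events)
  ok <- !is.na(times) & !is.na(events)
  times <- times[ok]; events <- events[ok]
  if (!any(events == 0)) {
    warning("no censored observations; follow-up undefined")
    return(c(median = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  }
  fit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1,
                           conf.type = "log-log")
  q <- stats::quantile(fit, probs = 0.5)
  c(median = unname(q$quantile), ci_low = unname(q$lower),
    ci_high = unname(q$upper))
}

#' Two-group log-rank test
#'
#' @param group_a,group_b Lists with `times` and `events`.
#' @return List with `statistic` (chi-square, 1 df) and `p` (two-sided).
#' @export
logrank_test <- function(group_a, group_b) {
  t_all <- c(group_a$times, group_b$times)
  e_all <- as.integer(c(group_a$events, group_b$events))
  g <- rep(c(0L, 1L), c(length(group_a$times), length(group_b$times)))
  ok <- !is.na(t_all) & !is.na(e_all)
  t_all <- t_all[ok]; e_all <- e_all[ok]; g <- g[ok]
  if (!length(t_all) || length(unique(g)) < 2) stop("both groups required")
  if (sum(e_all) == 0) {
    warning("no events in either group; log-rank statistic is 0")
    return(list(statistic = 0, p = 1))
  }
  if (any(tapply(e_all, g, sum) == 0))
    warning("a group has zero events")
  sd <- survival::survdiff(survival::Surv(t_all, e_all) ~ g)
  stat <- sd$chisq
  list(statistic = unname(stat),
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

effect_estimate <- function(kind, point, ci_low, ci_high, p, n_used) {
  stopifnot(is.na(ci_low) || is.na(ci_high) ||
              (ci_low <= point + 1e-9 && point <= ci_high + 1e-9))
  structure(list(kind = kind, point = point, ci_low = ci_low,
                 ci_high = ci_high, p = p, n_used = n_used),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s: %.2f [%.2f-%.2f], p = %.3g (n = %d)\n", x$kind,
              x$point, x$ci_low, x$ci_high, x$p, x$n_used))
  invisible(x)
}

#' Univariable Cox proportional-hazards effect
#'
#' Partial-likelihood fit with Breslow tie handling (switchable to Efron);
#' Wald 95% CI and p-value.
#'
#' @param times,events Follow-up times and event indicators.
#' @param covariate Binary (0/1) or continuous covariate.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return An `effect_estimate` of kind `hazard_ratio`.
#' @export
cox_hr <- function(times, events, covariate, ties = "breslow") {
  events <- as.integer(events)
  x <- if (is.character(covariate)) as.numeric(covariate == "1")
       else as.numeric(covariate)
  ok <- !is.na(times) & !is.na(events) & !is.na(x)
  times <- times[ok]; events <- events[ok]; x <- x[ok]
  if (sum(events) < 1) stop("need at least one event")
  if (length(unique(x)) < 2) stop("constant covariate")
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(times, events) ~ x, ties = ties))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(stats::vcov(fit))))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15 || se > 100)
    stop("Cox fit degenerate for covariate (possible separation)")
  effect_estimate("hazard_ratio", exp(beta), exp(beta - 1.96 * se),
                  exp(beta + 1.96 * se),
                  2 * stats::pnorm(-abs(beta / se)), length(times))
}

#' Odds of an outcome from counts
#'
#' `odds = successes / failures` with the Wald 95% CI
#' `exp(log(odds) +/- 1.96 * sqrt(1/successes + 1/failures))`.
#'
#' @param successes,failures Non-negative counts (sum >= 1).
#' @param haldane Apply the Haldane 0.5 correction when a count is zero?
#' @return An `effect_estimate` of kind `odds` (p is `NA`: no null here).
#' @export
logistic_odds <- function(successes, failures, haldane = FALSE) {
  stopifnot(successes >= 0, failures >= 0, successes + failures >= 1)
  n <- successes + failures
  if ((successes == 0 || failures == 0)) {
    if (!haldane)
      return(effect_estimate("odds", successes / failures, NA_real_,
                             NA_real_, NA_real_, n))
    successes <- successes + 0.5; failures <- failures + 0.5
  }
  odds <- successes / failures
  se <- sqrt(1 / successes + 1 / failures)
  effect_estimate("odds", odds, exp(log(odds) - 1.96 * se),
                  exp(log(odds) + 1.96 * se), NA_real_, n)
}

#' Univariable logistic-regression odds ratio
#'
#' Maximum-likelihood logistic regression of a binary outcome on one
#' covariate; Wald 95% CI and p on the log-odds scale. For a binary
#' covariate this equals the 2x2 cross-product odds ratio with the
#' classical Wald interval.
#'
#' @param outcome Binary outcome (0/1 or "0"/"1").
#' @param covariate Binary or continuous covariate.
#' @return An `effect_estimate` of kind `odds_ratio`.
#' @export
logistic_or <- function(outcome, covariate) {
  y <- if (is.character(outcome)) as.numeric(outcome == "1")
       else as.numeric(outcome)
  x <- if (is.character(covariate)) as.numeric(covariate == "1")
       else as.numeric(covariate)
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]
  if (length(unique(x)) < 2) stop("constant covariate")
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  beta <- unname(stats::coef(fit)[2])
  se <- unname(sqrt(diag(stats::vcov(fit)))[2])
  effect_estimate("odds_ratio", exp(beta), exp(beta - 1.96 * se),
                  exp(beta + 1.96 * se),
                  2 * stats::pnorm(-abs(beta / se)), length(y))
}

#' Shapiro-gated two-sample comparison of continuous values
#'
#' Both samples are tested for normality (Shapiro-Wilk, subsampled to 5000
#' with a fixed seed when larger). If both pass at alpha = 0.05 a two-sided
#' unpaired t-test is used, otherwise a two-sided Wilcoxon rank-sum test
#' with normal approximation, tie and continuity correction.
#'
#' @param a,b Numeric samples (n >= 3 non-missing each).
#' @return List with `test` (`"t"` or `"wilcoxon"`), `statistic`, `p`.
#' @export
compare_continuous <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) stop("need >= 3 values per sample")
  sub <- function(x) {
    if (length(x) <= 5000) return(x)
    restore <- local_rng(20240320L)
    on.exit(restore())
    sample(x, 5000)
  }
  normal <- function(x) {
    x <- sub(x)
    if (stats::sd(x) == 0) return(FALSE)
    stats::shapiro.test(x)$p.value >= 0.05
  }
  if (normal(a) && normal(b)) {
    tt <- stats::t.test(a, b)
    list(test = "t", statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))
    list(test = "wilcoxon", statistic = unname(wt$statistic), p = wt$p.value)
  }
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p by the probability-mass summation convention.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin; p = 1")
    return(1)
  }
  stats::fisher.test(tab)$p.value
}
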