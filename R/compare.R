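# Cohort comparison tables: baseline characteristics, outcome endpoints,
# alteration frequencies, co-occurrence differences, and the univariable
# risk-marker concordance analysis between an original cohort and one or
# more synthetic cohorts. Significance is two-sided at alpha = 0.05 with
# no multiplicity correction (optionally Benjamini-Hochberg).

#' Default univariable risk-marker panel
#'
#' The established favorable (normal karyotype, t(8;21), inv(16), NPM1,
#' CEBPA-bZIP), intermediate (FLT3-ITD, t(9;11)) and adverse markers
#' (complex karyotype, -5, del(5q), -7, -17, TP53, RUNX1, ASXL1), plus age.
#' @return Character vector of marker variable names.
#' @export
eln_marker_panel <- function() {
  c("normal_karyotype", "t_8_21", "inv_16", "NPM1", "CEBPA_bZIP",
    "FLT3_ITD", "t_9_11", "complex_karyotype", "minus5", "del_5q",
    "minus7", "minus17", "TP53", "RUNX1", "ASXL1", "age")
}

endpoint_vars <- function(schema) {
  unlist(schema$endpoints, use.names = FALSE)
}

fmt_continuous <- function(v) {
  obs <- v[!is.na(v)]
  if (!length(obs)) return("all missing")
  q <- stats::quantile(obs, c(0.25, 0.5, 0.75), type = 7)
  sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
}

fmt_level <- function(v, lv, n) {
  cnt <- sum(!is.na(v) & v == lv)
  sprintf("%d (%.1f)", cnt, 100 * cnt / n)
}

#' Baseline-characteristics comparison table
#'
#' Each synthetic cohort is tested pairwise against the original:
#' continuous variables via the Shapiro-gated test of
#' [compare_continuous()], categorical variables per level (level vs rest)
#' via Fisher's exact test. Denominators exclude missing values; rendered
#' percentages use the full cohort size.
#'
#' @param original Original [cohort_table()].
#' @param synthetics List of synthetic [cohort_table()]s (named or not).
#' @param variables Variables to compare (default: all non-endpoint
#'   variables).
#' @param adjust Apply Benjamini-Hochberg across the table's p-values?
#' @return Data frame of comparison rows with `p` and `significant`.
#' @export
baseline_table <- function(original, synthetics, variables = NULL,
                           adjust = FALSE) {
  if (inherits(synthetics, "cohort_table")) synthetics <- list(synthetics)
  if (is.null(variables))
    variables <- setdiff(schema_names(original$schema),
                         endpoint_vars(original$schema))
  rows <- list()
  for (ci in seq_along(synthetics)) {
    syn <- synthetics[[ci]]
    check_same_schema(original, syn)
    cname <- if (!is.null(names(synthetics)) && nzchar(names(synthetics)[ci]))
      names(synthetics)[ci] else syn$label
    for (vn in variables) {
      s <- original$schema$specs[[vn]]
      vo <- original$data[[vn]]; vs <- syn$data[[vn]]
      if (s$kind %in% c("continuous", "time")) {
        res <- compare_continuous(vo, vs)
        rows[[length(rows) + 1L]] <- data.frame(
          cohort = cname, variable = vn, level = NA_character_,
          original_summary = fmt_continuous(vo),
          synthetic_summary = fmt_continuous(vs),
          test_used = res$test, p = res$p)
      } else {
        for (lv in setdiff(s$categories, "na")) {
          tab <- matrix(c(sum(vo == lv, na.rm = TRUE),
                          sum(vo != lv, na.rm = TRUE),
                          sum(vs == lv, na.rm = TRUE),
                          sum(vs != lv, na.rm = TRUE)), 2)
          rows[[length(rows) + 1L]] <- data.frame(
            cohort = cname, variable = vn, level = lv,
            original_summary = fmt_level(vo, lv, original$n),
            synthetic_summary = fmt_level(vs, lv, syn$n),
            test_used = "fisher", p = fisher_exact(tab))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (adjust) out$p <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < 0.05
  rownames(out) <- NULL
  out
}

#' Outcome comparison table (CR, EFS, OS)
#'
#' Per cohort: CR count/percent and within-cohort odds with Wald CI
#' ([logistic_odds()]); Kaplan-Meier median and quartiles for EFS and OS.
#' Per synthetic cohort vs the original: Fisher p for CR, a pooled Cox
#' hazard ratio with a cohort indicator, and the log-rank p.
#'
#' @inheritParams baseline_table
#' @return Data frame with one row per cohort per endpoint block.
#' @export
outcome_table <- function(original, synthetics) {
  if (inherits(synthetics, "cohort_table")) synthetics <- list(synthetics)
  ep <- original$schema$endpoints
  cohorts <- c(list(original), synthetics)
  labels <- vapply(seq_along(cohorts), function(i) {
    if (i == 1) return("original")
    nm <- names(synthetics)[i - 1]
    if (!is.null(nm) && nzchar(nm)) nm else cohorts[[i]]$label
  }, character(1))
  rows <- list()
  for (i in seq_along(cohorts)) {
    ch <- cohorts[[i]]
    cr <- ch$data[[ep$cr]]
    n_cr <- sum(cr == "1", na.rm = TRUE)
    n_no <- sum(cr == "0", na.rm = TRUE)
    odds <- logistic_odds(n_cr, n_no)
    fisher_p <- NA_real_
    if (i > 1) {
      cr0 <- original$data[[ep$cr]]
      fisher_p <- fisher_exact(matrix(c(sum(cr0 == "1", na.rm = TRUE),
                                        sum(cr0 == "0", na.rm = TRUE),
                                        n_cr, n_no), 2))
    }
    row <- data.frame(cohort = labels[i], n = ch$n, cr_n = n_cr,
                      cr_percent = 100 * n_cr / ch$n,
                      cr_odds = odds$point, cr_odds_low = odds$ci_low,
                      cr_odds_high = odds$ci_high, cr_fisher_p = fisher_p)
    for (end in c("efs", "os")) {
      sv <- endpoint_surv(ch, end)
      km <- km_median_iqr(km_estimate(sv$times, sv$events))
      hr <- low <- high <- lr_p <- NA_real_
      if (i > 1) {
        sv0 <- endpoint_surv(original, end)
        pooled_t <- c(sv0$times, sv$times)
        pooled_e <- c(sv0$events, sv$events)
        ind <- rep(c(0, 1), c(length(sv0$times), length(sv$times)))
        est <- cox_hr(pooled_t, pooled_e, ind)
        hr <- est$point; low <- est$ci_low; high <- est$ci_high
        lr_p <- logrank_test(sv0, sv)$p
      }
      blk <- data.frame(km["median"], km["q1"], km["q3"], hr, low, high,
                        lr_p)
      names(blk) <- paste0(end, "_", c("median", "q1", "q3", "hr",
                                       "hr_low", "hr_high", "logrank_p"))
      row <- cbind(row, blk)
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Alteration frequency table with pairwise Fisher tests
#'
#' Percent carriers per cohort for each binary alteration, with two-sided
#' Fisher p per synthetic cohort against the original; `highly_significant`
#' flags p < 0.001.
#'
#' @inheritParams baseline_table
#' @param alterations Binary alteration variable names (default: the
#'   fixture alteration panel present in the schema).
#' @return Data frame, one row per alteration per synthetic cohort.
#' @export
alteration_frequencies <- function(original, synthetics,
                                   alterations = NULL) {
  if (inherits(synthetics, "cohort_table")) synthetics <- list(synthetics)
  if (is.null(alterations))
    alterations <- intersect(names(aml_alterations()),
                             schema_names(original$schema))
  rows <- list()
  for (ci in seq_along(synthetics)) {
    syn <- synthetics[[ci]]
    cname <- if (!is.null(names(synthetics)) && nzchar(names(synthetics)[ci]))
      names(synthetics)[ci] else syn$label
    for (a in alterations) {
      vo <- original$data[[a]]; vs <- syn$data[[a]]
      co <- sum(vo == "1", na.rm = TRUE); cs <- sum(vs == "1", na.rm = TRUE)
      p <- fisher_exact(matrix(c(co, sum(vo == "0", na.rm = TRUE),
                                 cs, sum(vs == "0", na.rm = TRUE)), 2))
      rows[[length(rows) + 1L]] <- data.frame(
        cohort = cname, alteration = a,
        percent_original = 100 * co / original$n,
        percent_synthetic = 100 * cs / syn$n,
        fisher_p = p, highly_significant = p < 0.001)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative co-occurrence difference matrix
#'
#' For each pair of binary alterations, the relative difference (percent)
#' between the synthetic and original proportion of patients carrying both,
#' `100 * (p_syn - p_orig) / max(p_orig, 1/n_orig)`, clamped to
#' `[-100, 100]`; the diagonal applies the same formula to the marginal
#' frequencies.
#'
#' @param original,syn [cohort_table()]s on one schema.
#' @param alterations Binary variable names (default as in
#'   [alteration_frequencies()]).
#' @return Symmetric matrix with entries in `[-100, 100]`.
#' @export
cooccurrence_diff <- function(original, syn, alterations = NULL) {
  if (is.null(alterations))
    alterations <- intersect(names(aml_alterations()),
                             schema_names(original$schema))
  if (length(alterations) < 2) stop("need at least 2 binary variables")
  eps <- 1 / original$n
  carrier <- function(cohort) {
    M <- vapply(alterations,
                function(a) !is.na(cohort$data[[a]]) &
                  cohort$data[[a]] == "1",
                logical(cohort$n))
    matrix(M, ncol = length(alterations),
           dimnames = list(NULL, alterations))
  }
  Mo <- carrier(original); Ms <- carrier(syn)
  po <- crossprod(Mo) / original$n    # pairwise co-occurrence proportions
  ps <- crossprod(Ms) / syn$n
  d <- 100 * (ps - po) / pmax(po, eps)
  pmin(pmax(d, -100), 100)
}

classify_concordance <- function(dir_real, dir_syn, sig_real, sig_syn) {
  opposite <- dir_real * dir_syn < 0
  if (opposite && (sig_real || sig_syn)) return("inverse")
  if (sig_real && sig_syn) return("concordant_significant")
  if (!sig_real && !sig_syn) return("concordant_nonsignificant")
  "significance_discordant"
}

#' Univariable risk-marker effect panel
#'
#' Per marker and endpoint: logistic odds ratio for CR, Cox hazard ratio
#' for EFS and OS, with Wald 95% CI and p.
#'
#' @param cohort A [cohort_table()].
#' @param markers Marker variable names (default [eln_marker_panel()]).
#' @param endpoints Subset of `c("cr", "efs", "os")`.
#' @return Data frame with one row per (marker, endpoint).
#' @export
univariable_panel <- function(cohort, markers = eln_marker_panel(),
                              endpoints = c("cr", "efs", "os")) {
  ep <- cohort$schema$endpoints
  missing_m <- setdiff(markers, schema_names(cohort$schema))
  if (length(missing_m))
    stop("markers absent from cohort: ", paste(missing_m, collapse = ", "))
  rows <- list()
  for (m in markers) {
    spec <- cohort$schema$specs[[m]]
    x <- cohort$data[[m]]
    if (spec$kind == "binary") {
      carriers <- sum(x == "1", na.rm = TRUE)
      if (carriers < 5)
        warning("marker '", m, "' has < 5 carriers; intervals will be wide")
    }
    for (end in endpoints) {
      est <- if (end == "cr") {
        logistic_or(cohort$data[[ep$cr]], x)
      } else {
        sv <- endpoint_surv(cohort, end)
        cox_hr(sv$times, sv$events, x)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        marker = m, endpoint = toupper(end), kind = est$kind,
        point = est$point, ci_low = est$ci_low, ci_high = est$ci_high,
        p = est$p, n_used = est$n_used)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Concordance of univariable effects between two cohorts
#'
#' Classifies every (marker, endpoint) pair by effect direction and
#' significance: `concordant_significant` (both significant, same
#' direction), `concordant_nonsignificant` (neither significant),
#' `significance_discordant` (same direction, one significant), `inverse`
#' (opposite directions with at least one significant).
#'
#' @param panel_real,panel_syn Panels from [univariable_panel()] with
#'   matching (marker, endpoint) keys.
#' @param alpha Significance threshold (default 0.05).
#' @return List with `cells` (one row per pair) and `summary` (counts per
#'   class, including `n_inverse`).
#' @export
concordance_matrix <- function(panel_real, panel_syn, alpha = 0.05) {
  key_r <- paste(panel_real$marker, panel_real$endpoint)
  key_s <- paste(panel_syn$marker, panel_syn$endpoint)
  if (!setequal(key_r, key_s) || anyDuplicated(key_r))
    stop("panels have mismatched (marker, endpoint) keys")
  panel_syn <- panel_syn[match(key_r, key_s), ]
  dir_r <- sign(log(panel_real$point))
  dir_s <- sign(log(panel_syn$point))
  sig_r <- panel_real$p < alpha
  sig_s <- panel_syn$p < alpha
  cls <- mapply(classify_concordance, dir_r, dir_s, sig_r, sig_s)
  cells <- data.frame(marker = panel_real$marker,
                      endpoint = panel_real$endpoint,
                      direction_real = dir_r, direction_syn = dir_s,
                      sig_real = sig_r, sig_syn = sig_s, class = cls)
  counts <- table(factor(cls, levels = c("concordant_significant",
                                         "concordant_nonsignificant",
                                         "significance_discordant",
                                         "inverse")))
  list(cells = cells,
       summary = as.data.frame(counts, responseName = "count"),
       n_inverse = unname(counts[["inverse"]]))
}
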