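# End-to-end study orchestration: simulate or load -> split -> (tune) ->
# fit -> sample -> evaluate fidelity, survival fidelity, privacy,
# comparison tables and concordance -> serialize a report bundle.

#' Build a pipeline run configuration
#'
#' The global seed fans out to fixed stage seeds (`seed + 1000 * stage
#' index`) so each stochastic stage is reproducible in isolation.
#'
#' @param seed Global integer seed.
#' @param n Original (fixture) cohort size.
#' @param synthetic_n Synthetic cohort size (default: same as `n`).
#' @param train_fraction Training fraction for the privacy split.
#' @param k_subsets Training subsets for the privacy assessment.
#' @param tune_budget Random-search trials for generator tuning (0 = use
#'   default hyperparameters).
#' @param fixture_config Optional [default_config()] override.
#' @param output_dir Optional directory; when non-`NULL`, all tables and
#'   reports are written there as CSV/JSON plus the config itself.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n = 1606L, synthetic_n = NULL,
                       train_fraction = 0.8, k_subsets = 4L,
                       tune_budget = 0L, fixture_config = NULL,
                       output_dir = NULL) {
  structure(list(seed = as.integer(seed), n = as.integer(n),
                 synthetic_n = as.integer(if (is.null(synthetic_n)) n
                                          else synthetic_n),
                 train_fraction = train_fraction,
                 k_subsets = as.integer(k_subsets),
                 tune_budget = as.integer(tune_budget),
                 fixture_config = fixture_config,
                 output_dir = output_dir,
                 stage_seeds = list(simulate = seed,
                                    split = seed + 1000L,
                                    fit = seed + 2000L,
                                    sample = seed + 3000L,
                                    partition = seed + 4000L,
                                    tune = seed + 5000L)),
            class = "run_config")
}

try_stage <- function(bundle, name, expr) {
  res <- tryCatch(expr, error = function(e) {
    warning("stage '", name, "' failed: ", conditionMessage(e))
    structure(list(error = conditionMessage(e)), class = "stage_error")
  })
  bundle[[name]] <- res
  bundle
}

#' Run the full synthetic-cohort study pipeline
#'
#' Simulates (or accepts) an original cohort, splits it, fits the copula
#' generator on the training part, samples a synthetic cohort, and
#' evaluates fidelity, survival fidelity (OS and EFS), privacy, baseline
#' and outcome comparison tables, alteration frequencies, co-occurrence
#' differences, and univariable concordance. Failure of one evaluation
#' stage does not abort the others.
#'
#' @param config A [run_config()].
#' @param original Optional [cohort_table()] to use instead of a simulated
#'   fixture.
#' @param synthetic Optional externally generated synthetic
#'   [cohort_table()]; when given, the generator stages are skipped.
#' @return A `report_bundle` list; written to `config$output_dir` when set.
#' @export
run_pipeline <- function(config = run_config(), original = NULL,
                         synthetic = NULL) {
  ss <- config$stage_seeds
  bundle <- list(config = config)
  if (is.null(original)) {
    fc <- if (is.null(config$fixture_config))
      default_config(ss$simulate) else config$fixture_config
    sim <- simulate_cohort(fc, n = config$n)
    original <- sim$cohort
    original$label <- "original"
    bundle$ground_truth <- sim$ground_truth
  }
  bundle$original <- original
  parts <- split_train_test(original, config$train_fraction, seed = ss$split)
  bundle$split <- list(n_train = parts$train$n, n_test = parts$test$n)

  if (is.null(synthetic)) {
    hp <- NULL
    if (config$tune_budget > 0) {
      tuned <- tune_generator(parts$train, parts$test,
                              budget = config$tune_budget, seed = ss$tune)
      bundle$tuning <- tuned
      hp <- tuned$best
    }
    model <- if (is.null(hp)) fit_generator(parts$train, seed = ss$fit)
             else fit_generator(parts$train, config = hp, seed = ss$fit)
    bundle$model_meta <- model$fit_meta
    synthetic <- sample_synthetic(model, config$synthetic_n,
                                  seed = ss$sample)
    bundle$model <- model
  }
  bundle$synthetic <- synthetic

  bundle <- try_stage(bundle, "fidelity",
                      fidelity_report(original, synthetic))
  bundle <- try_stage(bundle, "survival_fidelity_os",
                      survival_fidelity_report(original, synthetic, "os"))
  bundle <- try_stage(bundle, "survival_fidelity_efs",
                      survival_fidelity_report(original, synthetic, "efs"))
  bundle <- try_stage(bundle, "privacy",
                      privacy_report(synthetic, parts$train, parts$test,
                                     k = config$k_subsets,
                                     seed = ss$partition))
  bundle <- try_stage(bundle, "baseline",
                      baseline_table(original, list(synthetic),
                                     variables = setdiff(
                                       schema_names(original$schema),
                                       c(endpoint_vars(original$schema),
                                         intersect(names(aml_alterations()),
                                                   schema_names(
                                                     original$schema))))))
  bundle <- try_stage(bundle, "outcomes",
                      outcome_table(original, list(synthetic)))
  bundle <- try_stage(bundle, "alterations",
                      alteration_frequencies(original, list(synthetic)))
  bundle <- try_stage(bundle, "cooccurrence",
                      cooccurrence_diff(original, synthetic))
  bundle <- try_stage(bundle, "concordance", {
    pr <- univariable_panel(original)
    ps <- univariable_panel(synthetic)
    concordance_matrix(pr, ps)
  })
  class(bundle) <- "report_bundle"
  if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
  bundle
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bundle$config
  cfg$fixture_config <- NULL    # matrices serialize poorly; seed suffices
  jsonlite::write_json(unclass(cfg), file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  wr <- function(x, name) {
    if (inherits(x, "stage_error") || is.null(x)) return(invisible(NULL))
    if (is.data.frame(x))
      utils::write.csv(x, file.path(dir, paste0(name, ".csv")),
                       row.names = FALSE)
    else if (is.matrix(x))
      utils::write.csv(as.data.frame(x), file.path(dir, paste0(name,
                                                               ".csv")))
    else jsonlite::write_json(x, file.path(dir, paste0(name, ".json")),
                              auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  wr(bundle$fidelity[c("rsc", "bsm", "ltcs")], "fidelity")
  wr(bundle$survival_fidelity_os, "survival_fidelity_os")
  wr(bundle$survival_fidelity_efs, "survival_fidelity_efs")
  if (!inherits(bundle$privacy, "stage_error"))
    wr(unclass(bundle$privacy), "privacy")
  wr(bundle$baseline, "baseline_table")
  wr(bundle$outcomes, "outcome_table")
  wr(bundle$alterations, "alteration_frequencies")
  wr(bundle$cooccurrence, "cooccurrence_diff")
  if (!inherits(bundle$concordance, "stage_error")) {
    wr(bundle$concordance$cells, "concordance_cells")
    wr(bundle$concordance$summary, "concordance_summary")
  }
  writeLines(render_report(bundle), file.path(dir, "report.md"))
  invisible(dir)
}

fmt_score <- function(x) {
  if (is.null(x) || inherits(x, "stage_error")) "not computed" else
    sprintf("%.2f", x)
}

#' Render a report bundle as markdown
#'
#' One human-readable document with the metric scorecard, outcome and
#' baseline tables, the privacy assessment (with a prominent warning when
#' the breach flag is set), and the concordance summary.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @return Character vector of markdown lines.
#' @export
render_report <- function(bundle) {
  lines <- c("# Synthetic cohort evaluation report", "")
  lines <- c(lines, sprintf("Original cohort: n = %d; synthetic: n = %d.",
                            bundle$original$n, bundle$synthetic$n), "")
  f <- bundle$fidelity
  lines <- c(lines, "## Fidelity scorecard", "",
             "| metric | score |", "|---|---|",
             sprintf("| Regularized support coverage | %s |",
                     fmt_score(f$rsc)),
             sprintf("| Basic statistical measure | %s |",
                     fmt_score(f$bsm)),
             sprintf("| Log-transformed correlation score | %s |",
                     fmt_score(f$ltcs)))
  for (end in c("os", "efs")) {
    sf <- bundle[[paste0("survival_fidelity_", end)]]
    if (inherits(sf, "stage_error") || is.null(sf)) next
    lines <- c(lines,
               sprintf("| KM divergence (%s) | %s |", toupper(end),
                       fmt_score(sf$km_divergence_score)),
               sprintf("| Optimism (%s) | %s |", toupper(end),
                       fmt_score(sf$optimism_score)),
               sprintf("| Short-sightedness (%s) | %s |", toupper(end),
                       fmt_score(sf$short_sightedness_score)))
  }
  lines <- c(lines, "")
  pv <- bundle$privacy
  if (!is.null(pv) && !inherits(pv, "stage_error")) {
    lines <- c(lines, "## Privacy", "")
    if (isTRUE(pv$breach_flag) ||
        (!is.null(pv$exact_matches) && pv$exact_matches > 0))
      lines <- c(lines,
                 "**WARNING: potential privacy breach.** The leakage",
                 "coefficient exceeds the 0.05 threshold or synthetic rows",
                 "coincide with original records.", "")
    lines <- c(lines,
               sprintf("- leakage coefficient: %s (threshold %.2f)",
                       format(pv$leakage_coefficient), pv$threshold),
               sprintf("- avg min Hamming distance syn->train: %.4f",
                       pv$avg_min_dist_syn_train),
               sprintf("- avg min Hamming distance syn->test: %.4f",
                       pv$avg_min_dist_syn_test),
               sprintf("- median distances (train/test): %s / %s",
                       format(pv$median_dist_train),
                       format(pv$median_dist_test)),
               sprintf("- exact matches vs original: %d", pv$exact_matches),
               "")
  }
  cc <- bundle$concordance
  if (!is.null(cc) && !inherits(cc, "stage_error")) {
    lines <- c(lines, "## Univariable concordance", "",
               sprintf("- inverse effects: %d", cc$n_inverse))
    for (i in seq_len(nrow(cc$summary)))
      lines <- c(lines, sprintf("- %s: %d", cc$summary[i, 1],
                                cc$summary[i, "count"]))
    lines <- c(lines, "")
  }
  ot <- bundle$outcomes
  if (is.data.frame(ot)) {
    lines <- c(lines, "## Outcomes", "",
               "| cohort | CR % | median EFS | median OS |", "|---|---|---|---|")
    for (i in seq_len(nrow(ot)))
      lines <- c(lines, sprintf("| %s | %.1f | %.1f | %.1f |",
                                ot$cohort[i], ot$cr_percent[i],
                                ot$efs_median[i], ot$os_median[i]))
    lines <- c(lines, "")
  }
  lines
}
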