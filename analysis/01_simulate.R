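#!/usr/bin/env Rscript
# Stage 1: simulate the "original" trial cohort.
#
# Generates an AML-trial-like cohort of 1606 patients (demographics,
# blood counts, 50 correlated alterations, CR, censored EFS/OS) with
# known ground truth, and writes it in the standard CSV + schema-sidecar
# layout so later stages can reload it.

library(synthaml)

dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)
cfg <- default_config(seed = 20240301L)
sim <- simulate_cohort(cfg, n = 1606)
original <- sim$cohort
original$label <- "original"

write_cohort(original, "results/cohort/original.csv",
             schema_path = "results/cohort/schema.json")
gt <- sim$ground_truth
gt$config$latent_corr <- NULL         # large matrix; regenerable from seed
jsonlite::write_json(gt, "results/cohort/ground_truth.json",
                     auto_unbox = TRUE, digits = NA, force = TRUE)

s <- summarize_cohort(original)
med <- function(v) round(s$median[s$variable == v][1], 1)
cat("Simulated", original$n, "patients.\n")
cat("Median age", med("age"), "years; WBC", med("wbc"),
    "GPt/l; Plt", med("plt"), "GPt/l.\n")
cat("CR rate:",
    round(100 * mean(original$data$cr == "1", na.rm = TRUE), 1), "%\n")
sv <- km_estimate(original$data$os_time,
                  as.integer(original$data$os_event == "1"))
cat("KM median OS:", km_median_iqr(sv)[["median"]], "months",
    "(analytic target", round(gt$true_median_os, 1), "months)\n")
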