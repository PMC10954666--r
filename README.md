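# synthaml

Generation and evaluation of synthetic acute myeloid leukemia (AML)
clinical-trial cohorts.

Clinical trial data in rare aggressive diseases like AML is scarce, slow to
collect, and hard to share because of patient privacy. Synthetic cohorts —
artificial patient tables that mimic the joint distribution of a real trial
population — promise shareable data and synthetic control arms, but only if
three things can be demonstrated at once: the synthetic data is *faithful*
(distributions, correlations and survival behavior match), *useful*
(univariable risk associations keep their direction and significance), and
*private* (no synthetic patient is a disguised real one). `synthaml` is a
complete, seed-reproducible pipeline for that demonstration, aimed at
biostatisticians and methods researchers working with mixed-type, censored,
partially missing patient tables.

## What is inside

**Cohort model.** A patient-per-row table typed by a declarative schema
(continuous, binary, categorical, paired time/event variables; explicit
missing state), with two censored endpoints, event-free and overall
survival, satisfying EFS ≤ OS row-wise.

**Generator.** A Gaussian copula with empirical marginals. Each variable is
transformed to latent normal scores (rank scores for numerics, conditional
latent means for categoricals); the latent correlation of a pair is
recovered from the observed score covariance by inverting its Hermite-series
moment equation — a generalization of tetrachoric/polyserial estimation to
arbitrary mixed pairs. Missingness enters as independent mask dimensions
("an additional state per variable"). EFS is modeled indirectly through the
difference Δ = OS − EFS and reconstructed as

```
EFS = max(0, OS − max(0, Δ))
```

so EFS > OS is impossible by construction.

**Evaluation.** Normalized to [0, 1], where 1 means an exact copy:

| axis | scores |
|---|---|
| tabular fidelity | regularized support coverage (RSC), basic statistical measure (BSM), log-transformed correlation score (LTCS) |
| survival fidelity (per endpoint) | Kaplan-Meier divergence `1 − (1/T)∫|S_syn − S_real|`, optimism `1 − |(1/T)∫(S_syn − S_real)|`, short-sightedness on follow-up horizons |
| privacy | Hamming distances on decile-binned records; leakage coefficient `(syn→test)/(syn→train) − 1` with breach threshold 0.05; exact-match count |
| usability | per-cohort univariable odds/hazard ratios for a 16-marker risk panel, classified for direction/significance concordance |

**Fixture study.** A simulator of AML-trial-like cohorts (Table-1-style
marginals, 50 correlated alterations, logistic CR, cure-mixture Weibull OS,
joint administrative censoring, MCAR masking) with known ground truth, so
the whole pipeline is testable end to end without access to any real
cohort.

## Worked example

```r
library(synthaml)

sim <- simulate_cohort(default_config(seed = 42), n = 1606)
original <- sim$cohort
parts <- split_train_test(original, train_fraction = 0.8, seed = 43)
model <- fit_generator(parts$train, seed = 44)
synthetic <- sample_synthetic(model, n = 1606, seed = 45)

fid <- fidelity_report(original, synthetic)
round(unlist(fid[c("rsc", "bsm", "ltcs")]), 3)
#>   rsc   bsm  ltcs
#> 0.964 0.992 0.983

sfo <- survival_fidelity_report(original, synthetic, "os")
round(unlist(sfo[c("km_divergence_score", "optimism_score",
                   "short_sightedness_score")]), 3)
#>     km_divergence_score          optimism_score short_sightedness_score
#>                   0.965                   0.995                   0.998

priv <- privacy_report(synthetic, parts$train, parts$test, seed = 46)
priv$leakage_coefficient   #> -0.003   (threshold 0.05: no breach)
priv$exact_matches         #> 0

cc <- concordance_matrix(univariable_panel(original),
                         univariable_panel(synthetic))
cc$summary
#>                        Var1 count
#> 1    concordant_significant    14
#> 2 concordant_nonsignificant    26
#> 3   significance_discordant     8
#> 4                   inverse     0
```

Reading the output: the synthetic cohort covers ≈96% of the original's
per-variable category support, matches summary statistics (BSM 0.99) and
pairwise associations (LTCS 0.98), and its OS curve deviates from the
original's by ≈3.5% of the survival scale averaged over follow-up. It sits
as far from its training records as from held-out test records (leakage
−0.003, well under 0.05) with zero exact matches, and across 48
marker-endpoint pairs no risk association reverses direction — weakly
powered effects may lose significance (8 pairs), which is the expected
attenuation of a copula generator.

The same study as a sequence of narrated stages lives in `analysis/`
(`01_simulate.R` … `06_report.R`); each stage writes its tables under
`results/` and prints what it found.

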