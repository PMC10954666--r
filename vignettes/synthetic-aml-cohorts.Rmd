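---
title: "Generating and evaluating synthetic AML trial cohorts"
author: "synthaml"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and evaluating synthetic AML trial cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`synthaml` implements a complete study pipeline for synthetic clinical-trial
cohorts in acute myeloid leukemia (AML): a mixed-type patient table with an
explicit missing state and two censored, ordered time-to-event endpoints
(event-free survival EFS and overall survival OS) is used to fit a
generative model, sample a synthetic cohort of equal size, and evaluate it
along four axes — distributional fidelity, survival fidelity, privacy, and
concordance of univariable risk associations. Neural generative
architectures are out of scope by design; the package's generator is a
Gaussian copula with empirical marginals, which is deterministic given a
seed, runs on a desk in seconds, and exercises every evaluation stage. The
generator is exposed behind the same cohort interface as externally
produced synthetic data, so deposited cohorts can be scored by the
identical evaluation path.

# Data model

A cohort is a patient-per-row table typed by a declarative schema: each
variable is `continuous`, `binary`, `categorical`, `event_indicator`, or
`time`; every `time` variable is paired with exactly one event indicator;
missing values are a first-class state (reserved label `"na"` in category
space, empty cell in CSV). Two invariants are enforced at construction:
times are non-negative, and `EFS <= OS` in every row where both are
observed. Times are in months, laboratory values in their clinical units
(WBC and platelets in GPt/l, hemoglobin in mmol/l).

# The fixture generator (study conditions)

Because the underlying multicenter trial data cannot be redistributed, the
package ships a simulator that emulates that cohort's published structure
and serves as the "original" cohort for all tests. Its defaults are fixed
once:

* **Demographics / labs.** Age truncated normal (mean 55, sd 14, range
  18–90 years); WBC log-normal with median 19.5 GPt/l and a wide spread
  (sdlog 1.8); Hb log-normal median 5.9 mmol/l; platelets log-normal
  median 50 GPt/l. These put the simulated medians inside the published
  interquartile bands of the original cohort.
* **Alterations.** 50 binary molecular/cytogenetic alterations with
  frequencies between 0.5% and 35%, thresholded from a latent Gaussian
  with a hand-specified positive-definite correlation matrix encoding
  recurrent AML co-occurrence and exclusivity structure (e.g. NPM1 with
  FLT3-ITD and DNMT3A; TP53 with complex karyotype and the chromosome-5/7
  losses; mutual exclusivity of normal and complex karyotype).
* **Outcomes.** CR from a logistic model (marginal rate near 70%); OS from
  a Weibull proportional-hazards model (shape 0.9, scale 17.9 months) with
  a 20% long-survivor "cure" fraction, because a survival plateau is a
  mixture phenomenon a plain Weibull cannot produce; EFS as
  `max(0, OS - delta)` with a non-negative difference `delta` (10% point
  mass at zero, otherwise gamma with shape 1.2 and scale 13 months),
  calibrated so the marginal median EFS sits near 7 months against a
  median OS near 17.5 months. Every risk-panel marker carries a genuine
  effect in its guideline direction; effect sizes were chosen to be either
  clearly null or clearly detectable at the study scale, because
  borderline effects make direction/significance concordance a coin flip
  rather than a property of the generator.
* **Censoring.** One administrative draw per patient — uniform entry over
  a 72-month accrual window against a 126-month horizon — censors both
  endpoints jointly, which makes inconsistent follow-up (EFS follow-up
  exceeding OS follow-up) structurally impossible and puts the reverse
  Kaplan-Meier median follow-up near 90 months. A zero-length window
  observes nothing and censors everyone at 0.
* **Missingness.** Missing-completely-at-random per variable, 0–10%
  (defaults: 1–5% for labs and status variables, 2% for alterations and
  CR, none for survival), user-configurable. MCAR keeps the parameter
  recovery tests interpretable; the real cohort's mechanism is unknown.

The exact configuration plus derived true quantities (alteration
frequencies, latent correlations, log hazard ratios, the analytic marginal
median OS obtained by root-finding on the mixture survival averaged over
the linear-predictor distribution) are returned as ground truth alongside
every simulated cohort.

What the fixtures do *not* emulate: the real trials' joint distribution
beyond printed marginal bands and qualitative co-occurrence structure,
treatment-arm structure, non-random missingness, and measurement error.
Passing tests therefore demonstrate that the pipeline's machinery is
correct and well-calibrated under realistic conditions — not that any
specific real cohort would score identically.

# The copula generator

`fit_generator()` estimates, per variable, an empirical marginal with the
missing state as its own probability mass, and a latent Gaussian
dependence structure:

* Continuous and time variables become rank-based normal scores; their
  missingness is factorized into an independent Bernoulli mask that
  enters the latent vector as one extra dimension.
* Categorical variables (including binary alterations and event
  indicators) are placed at the conditional mean of the latent standard
  normal within their category's cumulative-probability interval
  (polyserial-style regression scores). Their missing state is factorized
  into a mask dimension exactly like the numeric case. An earlier design
  that appended `"na"` as the top interval of the same latent dimension
  was rejected: it manufactures a spurious joint-tail association between
  missingness and the top category, which measurably biased latent
  correlations downward.
* EFS time is never modeled directly. The survival block models OS time,
  both event indicators, and the rowwise difference `delta = OS - EFS`;
  sampling reconstructs `EFS = max(0, OS - max(0, delta))`, so `EFS <= OS`
  holds with probability one. This indirect construction is the package's
  answer to the logical flaw that arises when two coupled time-to-event
  variables are modeled independently.

**Latent correlation estimation.** The observed covariance between two
score columns is a known function of the latent correlation: expanding
each score function in Hermite polynomials (closed-form coefficients via
the identity `∫ He_k φ = He_{k-1} φ` at the interval edges) gives
`cov = Σ_k ρ^k f_k g_k / k!`, which is inverted per pair on a fine grid —
a generalization of tetrachoric/polyserial estimation to all mixed pairs.
For pairs of rare categories this moment curve is nearly flat and a plain
inversion amplifies sampling noise into extreme correlations, so each pair
receives the smallest-magnitude `ρ` whose implied covariance lies within a
quarter standard error of the observed one; informative pairs have tiny
standard errors and are essentially untouched. The assembled matrix is
repaired to the nearest positive-definite correlation matrix by eigenvalue
clipping at `1e-8` and rescaling to unit diagonal.

**Sampling** draws a latent multivariate normal, inverts the empirical
marginals (continuous values by type-7 quantile interpolation, hence
bounded to the observed training range — synthetic outliers beyond the
training support are impossible, a deliberate, documented fidelity
limitation), cuts categoricals at their cumulative probabilities, applies
the coupled masks, and reconstructs EFS.

**Hyperparameters** (all tunable via `tune_generator()`, a seeded random
search): latent shrinkage toward the identity (default 0), a uniform
jitter bandwidth on the copula scale at inversion time (default 0), and
additive category smoothing (default 0.5). The tuning objective averages,
with equal weights, support coverage restricted to CR, the Kaplan-Meier
divergence score for OS, and the basic statistical measure restricted to
the OS−EFS difference — the three quantities the study design singles
out. Equal weighting is a declared choice; nothing in the source material
fixes the weights.

# Evaluation metrics

All scores are normalized to [0, 1] with 1 attained exactly on an exact
copy; the named metrics follow the literature, but their precise formulas
are this package's own choices and are therefore stated here:

* **Regularized support coverage (RSC).** Per variable with category set
  C (continuous variables first decile-binned on the *original* cohort's
  edges): `S_v = mean_c min(1, p̃_syn(c) / p̃_real(c))` with
  Laplace-smoothed proportions `p̃(c) = (n_c + 1)/(N + |C|)`; overall
  score = mean over variables. Smoothing makes a missing rare category
  costly but never fatal.
* **Basic statistical measure (BSM).** Per numeric variable, min-max
  normalized by the original cohort's observed range:
  `clip(1 − |stat_real − stat_syn|)` averaged over mean, median, standard
  deviation, then over variables.
* **Log-transformed correlation score (LTCS).**
  `1 − mean |A_real − A_syn|` over defined off-diagonal pairs of an
  association matrix: |Pearson r| on log1p-transformed values for numeric
  pairs (log1p applied only when the variable is non-negative), Cramér's
  V for categorical pairs, correlation ratio for mixed pairs,
  pairwise-complete so the missing state never poses as a numeric level.
* **Survival fidelity** per endpoint: with both Kaplan-Meier curves
  carried forward flat beyond their last observation and T the original
  cohort's largest observed time, KM divergence = `1 − (1/T)∫|ΔS|`,
  optimism score = `1 − |(1/T)∫(S_syn − S_real)|` (the signed integral is
  reported too; positive means the synthetic curve is optimistic), and
  short-sightedness = `1 − max(0, (T_real − T_syn)/T_real)` on the
  observed horizons, with no penalty for overshoot. Exact step-function
  integration over the union grid of event times; the grid choice is
  recorded in the report.

# Privacy assessment

Records are compared in a fully categorical space: numeric variables are
binned into 10 categories at the empirical deciles of the original
cohort (equal-width bins would collapse the heavily skewed blood counts
into one bin), missing maps to `"na"`, and `"na"` equals `"na"` under the
Hamming distance. The original training part (80%) is partitioned into
four seeded subsets matching the test-set size (sized as equally as
possible when the arithmetic does not divide evenly; with 1606 patients:
four subsets of 321 from 1284 training rows). The leakage coefficient is

```
(syn -> test) / (syn -> train) - 1
```

where `syn -> train` averages the subset-level mean minimum distances (the
union would mechanically shrink minima and unbalance the comparison) and
values above 0.05 flag a potential breach. Reported medians are pooled
per-record minima. The "original cohort" baseline column uses
test-to-subset distances (train side) and subset-1-to-test (test side) — a
declared convention, since no canonical construction exists. Exact-match
counting runs on raw, un-binned values with missing-equals-missing; it is
the complementary check, because a verbatim copy of the *entire* original
cohort is equidistant to training and test records and thus invisible to
the ratio.

# Statistical machinery and conventions

Standard estimators are delegated to the survival package and stats:
Kaplan-Meier via the product-limit estimator (median and quartiles by the
first-crossing convention; undefined when the curve plateaus above the
level), reverse Kaplan-Meier follow-up with a log-log CI, two-group
log-rank, Cox proportional hazards with **Breslow** tie handling
(switchable to Efron; Breslow matches the original analysis software's
default), logistic regression for odds ratios with Wald intervals, and
Fisher's exact test with the probability-mass-summation two-sided
convention. Continuous two-sample comparisons are gated by Shapiro-Wilk at
alpha 0.05 on both samples (subsampled to 5000 with a fixed seed, the
test's validity range): t-test if both pass, otherwise Wilcoxon rank-sum
with normal approximation, tie and continuity correction. The published
outcome table's "OR" row is reproduced as the within-cohort odds of CR
(successes/failures with a Wald CI), which matches the printed values
exactly, rather than as a covariate-adjusted ratio. Baseline tables test
multi-level categoricals per level (level vs rest, Fisher), matching the
published per-level p-values; denominators exclude missing values while
rendered percentages use full cohort size, with missing counts reported —
this makes the ambiguous-denominator rows auditable. Significance is
two-sided at alpha 0.05 without multiplicity correction throughout, with
an optional Benjamini-Hochberg flag.

The univariable concordance analysis classifies each (marker, endpoint)
pair of the 16-marker risk panel (15 guideline markers plus age) by
direction and significance; *inverse* — opposite directions with at least
one side significant — is the failure mode of interest. The
classification is a pure function of four flags and is tested over all 16
combinations.

# Numerical choices and degenerate inputs

Quartiles use linear interpolation (R type 7) everywhere, recorded in the
summary metadata. Bin edges are forced monotone under ties; a zero-spread
variable collapses to one bin with a warning. A variable that is entirely
missing is excluded from the generator with a warning and sampled as
all-missing. Cox fits that yield non-finite or exploding coefficients
(separation) raise an error naming the problem; a constant covariate is
rejected up front. Zero cells in odds computations leave the CI undefined
unless the Haldane correction is requested; a zero-margin contingency
table returns p = 1 with a warning. The co-occurrence difference matrix
uses `100·(p_syn − p_orig)/max(p_orig, 1/n)` clamped to ±100%, so a pair
absent from the original cannot divide by zero.

# Reproducibility

Every stochastic stage takes an explicit integer seed; the pipeline
orchestrator fans a global seed out as `seed + 1000·stage` (simulate,
split, fit, sample, partition, tune) so stages are reproducible in
isolation and never share streams. Fitting itself is deterministic given
the data. Rerunning a serialized run configuration reproduces every
number exactly.

# Known limitations

* Synthetic continuous values cannot exceed the training range
  (empirical-quantile inversion); real generative models show analogous
  truncation behavior.
* Univariable hazard ratios in sampled cohorts are mildly attenuated
  (roughly 10–25% on the log scale for moderate effects): a Gaussian
  copula matched to pairwise rank dependence cannot exactly reproduce a
  proportional-hazards relationship, and censoring times share the rank
  scale with event times. Strong effects keep direction and significance;
  weak rare-marker effects can drop below the significance threshold in
  the synthetic cohort (a significance-discordant, not inverse, outcome),
  and in roughly one replicate in twenty a borderline rare marker flips
  direction non-significantly.
* Latent correlations between two *rare* binary variables are weakly
  identified at trial-scale n; the parsimony rule keeps them near zero
  rather than letting them saturate, so rare-pair co-occurrence is the
  least faithful part of a sampled cohort — mirroring the deviations the
  evaluation surfaces for low-frequency alterations.
* The distance-based privacy coefficient measures relative closeness to
  training vs test records only; it is not a membership-inference attack
  model and carries no differential-privacy guarantee.

# Problem sizes used by the test suite

Monte-Carlo property tests run at the sizes their tolerances were derived
for: 20,000-row fixtures for frequency (±0.01), correlation (±0.05 among
informative pairs), Kolmogorov-Smirnov (≤0.02) and hazard-ratio recovery;
the desk-scale study at the original size of 1606 (80/20 split, four
privacy subsets of 321); brute-force oracles for Kaplan-Meier, Fisher,
Hamming minima and co-occurrence counting on inputs of a few hundred
rows; 200-replicate coverage checks for Wald intervals. The complete
suite runs in about a minute on one core.
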