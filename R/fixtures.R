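# AML-trial-like fixture cohorts with known ground truth.
#
# The generator emulates the structure of a pooled intensively treated adult
# AML trial cohort: demographics and blood counts with heavy right skew,
# 50 correlated binary molecular/cytogenetic alterations, a CR indicator
# driven by a logistic model, overall survival from a proportional-hazards
# Weibull with a long-survivor ("cure") plateau, event-free survival derived
# from OS minus a non-negative difference, joint administrative censoring,
# and per-variable MCAR masking applied last.

#' Names of the 50 fixture alterations, grouped as in myeloid panels
#' @return Named character vector mapping alteration name to functional group.
#' @export
aml_alterations <- function() {
  c(ASXL1 = "epigenetic", ASXL2 = "epigenetic", BCOR = "epigenetic",
    BCORL1 = "epigenetic", DNMT3A = "epigenetic", EZH2 = "epigenetic",
    IDH1 = "epigenetic", IDH2 = "epigenetic", KDM6A = "epigenetic",
    KMT2A_PTD = "epigenetic", TET2 = "epigenetic",
    RAD21 = "cohesin", SMC1A = "cohesin", SMC3 = "cohesin", STAG2 = "cohesin",
    CEBPA_bZIP = "transcription", CUX1 = "transcription",
    ETV6 = "transcription", GATA2 = "transcription", IKZF1 = "transcription",
    MYC = "transcription", PHF6 = "transcription", RUNX1 = "transcription",
    WT1 = "transcription",
    NPM1 = "npm1_tp53", TP53 = "npm1_tp53",
    BRAF = "signaling", CBL = "signaling", CSF3R = "signaling",
    FLT3_ITD = "signaling", FLT3_TKD = "signaling", JAK2 = "signaling",
    KIT = "signaling", KRAS = "signaling", NRAS = "signaling",
    PTPN11 = "signaling", RIT1 = "signaling",
    SF3B1 = "spliceosome", SRSF2 = "spliceosome", U2AF1 = "spliceosome",
    ZRSR2 = "spliceosome",
    normal_karyotype = "cytogenetic", complex_karyotype = "cytogenetic",
    t_8_21 = "cytogenetic", inv_16 = "cytogenetic", t_9_11 = "cytogenetic",
    minus5 = "cytogenetic", del_5q = "cytogenetic", minus7 = "cytogenetic",
    minus17 = "cytogenetic")
}

#' The fixture cohort schema
#'
#' Clinical variables (age, sex, AML status, extramedullary disease, WBC,
#' Hb, Plt), the 50 binary alterations, the CR endpoint and the paired
#' EFS/OS time-to-event endpoints.
#' @return A [cohort_schema()].
#' @export
aml_schema <- function() {
  alt <- names(aml_alterations())
  specs <- c(
    list(variable_spec("age", "continuous", units = "years"),
         variable_spec("sex", "categorical",
                       categories = c("female", "male")),
         variable_spec("aml_status", "categorical",
                       categories = c("de_novo", "secondary",
                                      "therapy_associated")),
         variable_spec("extramedullary", "binary"),
         variable_spec("wbc", "continuous", units = "GPt/l"),
         variable_spec("hb", "continuous", units = "mmol/l"),
         variable_spec("plt", "continuous", units = "GPt/l")),
    lapply(alt, function(a) variable_spec(a, "binary")),
    list(variable_spec("cr", "binary"),
         variable_spec("efs_time", "time", units = "months",
                       pair = "efs_event"),
         variable_spec("efs_event", "event_indicator"),
         variable_spec("os_time", "time", units = "months",
                       pair = "os_event"),
         variable_spec("os_event", "event_indicator")))
  cohort_schema(specs, cr = "cr",
                efs = c("efs_time", "efs_event"),
                os = c("os_time", "os_event"))
}

default_alteration_freqs <- function() {
  f <- c(ASXL1 = 0.07, ASXL2 = 0.02, BCOR = 0.04, BCORL1 = 0.03,
         DNMT3A = 0.26, EZH2 = 0.02, IDH1 = 0.08, IDH2 = 0.10,
         KDM6A = 0.02, KMT2A_PTD = 0.05, TET2 = 0.10,
         RAD21 = 0.03, SMC1A = 0.02, SMC3 = 0.02, STAG2 = 0.05,
         CEBPA_bZIP = 0.06, CUX1 = 0.02, ETV6 = 0.02, GATA2 = 0.03,
         IKZF1 = 0.02, MYC = 0.01, PHF6 = 0.03, RUNX1 = 0.10, WT1 = 0.08,
         NPM1 = 0.30, TP53 = 0.08,
         BRAF = 0.01, CBL = 0.02, CSF3R = 0.02, FLT3_ITD = 0.22,
         FLT3_TKD = 0.07, JAK2 = 0.02, KIT = 0.04, KRAS = 0.05,
         NRAS = 0.12, PTPN11 = 0.06, RIT1 = 0.01,
         SF3B1 = 0.04, SRSF2 = 0.06, U2AF1 = 0.03, ZRSR2 = 0.02,
         normal_karyotype = 0.34, complex_karyotype = 0.10,
         t_8_21 = 0.05, inv_16 = 0.05, t_9_11 = 0.03,
         minus5 = 0.02, del_5q = 0.04, minus7 = 0.06, minus17 = 0.03)
  stopifnot(identical(names(f), names(aml_alterations())))
  f
}

# latent dimension order used by the fixture copula
fixture_latent_names <- function() {
  c("age", "wbc", "hb", "plt", "sex", "aml_status", "extramedullary",
    names(aml_alterations()))
}

default_latent_corr <- function() {
  nm <- fixture_latent_names()
  R <- diag(length(nm)); dimnames(R) <- list(nm, nm)
  set_pair <- function(a, b, r) {
    R[a, b] <<- r; R[b, a] <<- r
  }
  # recurrent AML co-occurrence / exclusivity structure
  set_pair("NPM1", "FLT3_ITD", 0.40)
  set_pair("NPM1", "DNMT3A", 0.35)
  set_pair("NPM1", "normal_karyotype", 0.35)
  set_pair("NPM1", "complex_karyotype", -0.30)
  set_pair("NPM1", "RUNX1", -0.30)
  set_pair("NPM1", "TP53", -0.30)
  set_pair("TP53", "complex_karyotype", 0.50)
  set_pair("TP53", "minus5", 0.30)
  set_pair("TP53", "minus7", 0.30)
  set_pair("TP53", "minus17", 0.35)
  set_pair("complex_karyotype", "normal_karyotype", -0.55)
  set_pair("complex_karyotype", "minus5", 0.40)
  set_pair("complex_karyotype", "minus7", 0.40)
  set_pair("complex_karyotype", "del_5q", 0.40)
  set_pair("RUNX1", "ASXL1", 0.30)
  set_pair("RUNX1", "SRSF2", 0.25)
  set_pair("SRSF2", "TET2", 0.25)
  set_pair("t_8_21", "KIT", 0.25)
  set_pair("t_8_21", "normal_karyotype", -0.30)
  set_pair("inv_16", "normal_karyotype", -0.30)
  set_pair("age", "TP53", 0.15)
  set_pair("age", "SRSF2", 0.20)
  set_pair("age", "NPM1", 0.05)
  set_pair("wbc", "FLT3_ITD", 0.25)
  set_pair("wbc", "NPM1", 0.15)
  nearest_correlation(R)
}

#' Default fixture configuration
#'
#' Marginal targets follow a pooled adult AML trial population: age
#' truncated normal (mean 55, sd 14, range 18-90 years), WBC log-normal
#' with median 19.5 GPt/l, Hb median 5.9 mmol/l, Plt median 50 GPt/l;
#' alteration frequencies between 0.5% and 35%; CR logistic model with
#' marginal rate near 70%; Weibull proportional-hazards OS with a 20%
#' long-survivor plateau and median near 17.5 months; administrative
#' censoring horizon 126 months with a 72-month accrual window.
#'
#' @param seed Integer seed stored in the config; all simulation draws
#'   derive from it.
#' @return A `fixture_config` list.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    n = 1606L,
    marginals = list(
      age = list(dist = "truncnorm", mean = 55, sd = 14, lower = 18,
                 upper = 90),
      wbc = list(dist = "lognormal", meanlog = log(19.5), sdlog = 1.80),
      hb  = list(dist = "lognormal", meanlog = log(5.9),  sdlog = 0.40),
      plt = list(dist = "lognormal", meanlog = log(50),   sdlog = 0.93),
      sex = list(p_male = 0.522),
      aml_status = list(p = c(de_novo = 0.84, secondary = 0.12,
                              therapy_associated = 0.04)),
      extramedullary = list(p = 0.139)),
    alteration_freqs = default_alteration_freqs(),
    latent_corr = default_latent_corr(),
    # every risk-panel marker carries a genuine effect in its guideline
    # direction (favorable negative log-HR / positive log-OR for CR)
    cr_model = list(intercept = 0.95,
                    coef = c(age_z = -0.50, normal_karyotype = 0.20,
                             t_8_21 = 0.40, inv_16 = 0.40, NPM1 = 0.50,
                             CEBPA_bZIP = 0.35, FLT3_ITD = -0.15,
                             t_9_11 = -0.40, complex_karyotype = -0.80,
                             minus5 = -0.40, del_5q = -0.45,
                             minus7 = -0.45, minus17 = -0.40,
                             TP53 = -1.20, RUNX1 = -0.60, ASXL1 = -0.25)),
    os_model = list(shape = 0.9, scale = 17.9,
                    coef = c(age_z = 0.35, normal_karyotype = -0.25,
                             t_8_21 = -0.45, inv_16 = -0.45, NPM1 = -0.30,
                             CEBPA_bZIP = -0.40, FLT3_ITD = 0.45,
                             t_9_11 = 0.55, complex_karyotype = 0.50,
                             minus5 = 0.50, del_5q = 0.35, minus7 = 0.45,
                             minus17 = 0.40, TP53 = 0.70, RUNX1 = 0.30,
                             ASXL1 = 0.30),
                    cure_fraction = 0.20),
    delta_model = list(p_zero = 0.10, shape = 1.2, scale = 13),
    censoring = list(horizon = 126, entry_window = 72),
    missing_rates = c(age = 0, sex = 0, aml_status = 0.01,
                      extramedullary = 0.05, wbc = 0.01, hb = 0.03,
                      plt = 0.03, alterations = 0.02, cr = 0.02)),
    class = "fixture_config")
}

local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

# survival function of the cure-mixture Weibull given a linear predictor
mixture_surv <- function(t, lp, os_model) {
  sw <- exp(-(t / os_model$scale)^os_model$shape * exp(lp))
  os_model$cure_fraction + (1 - os_model$cure_fraction) * sw
}

# deterministic marginal median OS: root of mean survival over the linear
# predictor distribution (fixed internal quadrature sample)
analytic_median_os <- function(config, n_quad = 50000L) {
  restore <- local_rng(config$seed + 104729L)
  on.exit(restore())
  lat <- draw_latent(config, n_quad)
  lp <- fixture_lp(lat, config$os_model$coef, config)
  f <- function(t) mean(mixture_surv(t, lp, config$os_model)) - 0.5
  if (f(1000) > 0) return(NA_real_)   # plateau above 0.5: median undefined
  stats::uniroot(f, c(0.01, 1000), tol = 1e-6)$root
}

# draw the latent MVN and transform to observed scales (no outcomes yet)
draw_latent <- function(config, n) {
  nm <- fixture_latent_names()
  R <- config$latent_corr
  L <- chol(R)
  Z <- matrix(stats::rnorm(n * length(nm)), n) %*% L
  colnames(Z) <- nm
  U <- stats::pnorm(Z)
  m <- config$marginals
  a <- m$age
  plo <- stats::pnorm((a$lower - a$mean) / a$sd)
  phi <- stats::pnorm((a$upper - a$mean) / a$sd)
  age <- a$mean + a$sd * stats::qnorm(plo + U[, "age"] * (phi - plo))
  wbc <- exp(m$wbc$meanlog + m$wbc$sdlog * Z[, "wbc"])
  hb  <- exp(m$hb$meanlog  + m$hb$sdlog  * Z[, "hb"])
  plt <- exp(m$plt$meanlog + m$plt$sdlog * Z[, "plt"])
  sex <- ifelse(U[, "sex"] < m$sex$p_male, "male", "female")
  pc <- cumsum(m$aml_status$p)
  aml_status <- names(m$aml_status$p)[findInterval(U[, "aml_status"],
                                                   pc) + 1L]
  extramedullary <- ifelse(U[, "extramedullary"] < m$extramedullary$p,
                           "1", "0")
  alt <- names(aml_alterations())
  A <- matrix("0", n, length(alt), dimnames = list(NULL, alt))
  for (g in alt)
    A[U[, g] < config$alteration_freqs[[g]], g] <- "1"
  cbind(data.frame(age = age, sex = sex, aml_status = aml_status,
                   extramedullary = extramedullary, wbc = wbc, hb = hb,
                   plt = plt, stringsAsFactors = FALSE),
        as.data.frame(A, stringsAsFactors = FALSE))
}

# linear predictor over centered covariates named in coef
fixture_lp <- function(lat, coef, config) {
  lp <- rep(0, nrow(lat))
  for (nm in names(coef)) {
    if (nm == "age_z") {
      x <- (lat$age - config$marginals$age$mean) / config$marginals$age$sd
    } else {
      x <- as.numeric(lat[[nm]] == "1") - config$alteration_freqs[[nm]]
    }
    lp <- lp + coef[[nm]] * x
  }
  lp
}

#' Simulate a fixture cohort with ground truth
#'
#' Rows are drawn as latent multivariate normal, thresholded to binaries and
#' transformed to continuous marginals; CR from a logistic model; OS from a
#' cure-mixture Weibull proportional-hazards model; EFS as OS minus a
#' non-negative difference, clipped at zero; joint administrative censoring
#' from one entry draw; MCAR masking last. EFS <= OS holds in every row.
#'
#' @param config A [default_config()]-style `fixture_config`.
#' @param n Cohort size (defaults to `config$n`).
#' @return List with `cohort` (a [cohort_table()]) and `ground_truth`
#'   (config plus derived true quantities, for recovery tests).
#' @export
simulate_cohort <- function(config, n = config$n) {
  if (n < 1) stop("n must be >= 1")
  ev <- eigen(config$latent_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("latent_corr is not positive definite")
  restore <- local_rng(config$seed)
  on.exit(restore())

  lat <- draw_latent(config, n)

  # CR
  lp_cr <- config$cr_model$intercept + fixture_lp(lat, config$cr_model$coef,
                                                  config)
  cr <- ifelse(stats::runif(n) < stats::plogis(lp_cr), "1", "0")

  # OS event time (cure-mixture Weibull PH)
  osm <- config$os_model
  lp_os <- fixture_lp(lat, osm$coef, config)
  cured <- stats::runif(n) < osm$cure_fraction
  u <- stats::runif(n)
  t_os <- osm$scale * (-log(u) / exp(lp_os))^(1 / osm$shape)
  t_os[cured] <- Inf

  # EFS via the non-negative difference to OS
  dm <- config$delta_model
  delta <- ifelse(stats::runif(n) < dm$p_zero, 0,
                  stats::rgamma(n, shape = dm$shape, scale = dm$scale))
  t_efs <- pmax(0, t_os - delta)
  t_efs[cured] <- Inf

  # one censoring draw per patient governs both endpoints
  cw <- config$censoring
  cens <- stats::runif(n, max(0, cw$horizon - cw$entry_window), cw$horizon)
  if (cw$horizon == 0) cens <- rep(0, n)
  # a zero-length follow-up window observes nothing: censored at 0
  os_time <- pmin(t_os, cens)
  os_event <- ifelse(t_os <= cens & cens > 0, "1", "0")
  efs_time <- pmin(t_efs, cens)
  efs_event <- ifelse(t_efs <= cens & cens > 0, "1", "0")

  data <- cbind(lat,
                data.frame(cr = cr,
                           efs_time = round(efs_time, 1),
                           efs_event = efs_event,
                           os_time = round(os_time, 1),
                           os_event = os_event,
                           stringsAsFactors = FALSE))

  # MCAR masking, applied last
  mr <- config$missing_rates
  rate_for <- function(v) {
    if (v %in% names(mr)) mr[[v]]
    else if (v %in% names(aml_alterations())) mr[["alterations"]]
    else 0
  }
  for (v in setdiff(names(data),
                    c("efs_time", "efs_event", "os_time", "os_event"))) {
    r <- rate_for(v)
    if (r > 0) data[[v]][stats::runif(n) < r] <- NA
  }

  cohort <- cohort_table(data, aml_schema(), label = "fixture")
  gt <- list(config = config,
             true_alteration_freqs = config$alteration_freqs,
             true_latent_corr = config$latent_corr,
             true_log_hr = config$os_model$coef,
             true_median_age = config$marginals$age$mean,
             true_median_wbc = exp(config$marginals$wbc$meanlog),
             true_median_plt = exp(config$marginals$plt$meanlog),
             true_median_os = analytic_median_os(config))
  list(cohort = cohort, ground_truth = gt)
}

#' Split a cohort into disjoint train/test parts
#'
#' Seeded shuffle; the training part gets `floor(n * train_fraction)` rows,
#' the test part the remainder. Together the parts contain every input row
#' exactly once.
#'
#' @param cohort A [cohort_table()].
#' @param train_fraction Fraction in (0, 1) assigned to training.
#' @param seed Integer seed for the shuffle.
#' @return List with `train` and `test` cohort tables.
#' @export
split_train_test <- function(cohort, train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (cohort$n < 2) stop("need at least 2 rows to split")
  restore <- local_rng(seed)
  on.exit(restore())
  idx <- sample.int(cohort$n)
  n_train <- floor(cohort$n * train_fraction)
  tr <- sort(idx[seq_len(n_train)])
  te <- sort(idx[-seq_len(n_train)])
  list(train = cohort_table(cohort$data[tr, , drop = FALSE], cohort$schema,
                            label = paste0(cohort$label, ":train")),
       test = cohort_table(cohort$data[te, , drop = FALSE], cohort$schema,
                           label = paste0(cohort$label, ":test")))
}
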