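# Gaussian-copula tabular generator with empirical marginals.
#
# Modeling choices mirror the study design this package evaluates:
# missingness is an explicit state per variable; overall survival is
# modeled directly while event-free survival is reconstructed from the
# non-negative difference OS - EFS, which makes EFS > OS impossible by
# construction; hyperparameters are tuned against CR, OS and the
# difference variable.

#' Reconstruct EFS from OS and the sampled difference
#'
#' `efs = max(0, os_time - max(0, delta))`; the clipping is the contract
#' guaranteeing `efs <= os_time` for every sampled row.
#'
#' @param os_time OS time in months (non-negative).
#' @param delta Sampled OS - EFS difference, any value.
#' @return EFS time in months.
#' @export
reconstruct_efs <- function(os_time, delta) {
  pmax(0, os_time - pmax(0, delta))
}

#' Nearest positive-definite correlation matrix
#'
#' Eigenvalue clipping at `eps` followed by rescaling to unit diagonal.
#' Idempotent on matrices that are already valid correlation matrices.
#'
#' @param m Symmetric square matrix.
#' @param eps Eigenvalue floor.
#' @return Positive-definite correlation matrix with unit diagonal.
#' @export
nearest_correlation <- function(m, eps = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("input must be square")
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  out <- e$vectors %*% diag(vals, nrow = length(vals)) %*% t(e$vectors)
  out <- stats::cov2cor(out)
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(m)
  out
}

# Normal scores for one variable. Continuous: rank-based normal scores.
# Categorical (incl. binary / event indicator / mask): the conditional
# mean of the latent standard normal within the category's
# cumulative-probability interval (polyserial-style regression scores).
# The score variance of a categorical equals its between-category
# variance share lambda = sum_c p_c * m_c^2, which is also the exact
# attenuation factor of its covariance with any other latent dimension;
# fit_generator divides it back out.
variable_scores <- function(v, spec, probs = NULL) {
  n <- length(v)
  z <- rep(NA_real_, n)
  if (spec$kind %in% c("continuous", "time") || is.null(probs)) {
    obs <- !is.na(v)
    m <- sum(obs)
    if (m > 0) {
      r <- rank(v[obs], ties.method = "average")
      z[obs] <- stats::qnorm((r - 0.5) / m)
    }
    return(z)
  }
  m_cat <- category_latent_means(probs)
  m_cat[match(v, names(probs))]
}

# truncated-normal means of the latent intervals implied by category
# cumulative probabilities, and the between-category variance share
category_latent_means <- function(probs) {
  cum <- pmin(pmax(cumsum(probs), 1e-12), 1 - 1e-12)
  lo <- c(0, cum[-length(cum)])
  a <- stats::qnorm(lo); b <- stats::qnorm(cum)
  m <- (stats::dnorm(a) - stats::dnorm(b)) / pmax(probs, 1e-12)
  names(m) <- names(probs)
  m
}

category_lambda <- function(probs) {
  m <- category_latent_means(probs)
  sum(probs * m^2)
}

# Hermite coefficients f_k = E[score(z) He_k(z)], k = 1..K, of the
# step-function score implied by the category intervals. Uses the identity
# int_a^b He_k(z) phi(z) dz = He_{k-1}(a) phi(a) - He_{k-1}(b) phi(b),
# so the coefficients are closed-form. For a pair of latent dimensions
# with correlation rho the observed score covariance is
#   sum_k rho^k f_k g_k / k!
# which fit_generator inverts per pair to recover rho exactly (tetrachoric
# / polyserial estimation generalized to all mixed pairs).
category_hermite_coefs <- function(probs, K = 8L) {
  m <- category_latent_means(probs)
  cum <- pmin(pmax(cumsum(probs), 1e-12), 1 - 1e-12)
  edges <- stats::qnorm(c(0, cum))          # interval bounds, +-Inf safe
  phi <- stats::dnorm(edges)                # 0 at +-Inf
  he <- matrix(0, K, length(edges))         # He_{k-1}(edges), k = 1..K
  he[1, ] <- 1
  if (K >= 2) he[2, ] <- edges
  if (K >= 3) for (k in 3:K)
    he[k, ] <- edges * he[k - 1, ] - (k - 2) * he[k - 2, ]
  he[!is.finite(he)] <- 0                   # killed by phi = 0 anyway
  g <- he * rep(phi, each = K)              # He_{k-1}(z) phi(z) at edges
  f <- numeric(K)
  for (k in seq_len(K))
    f[k] <- sum(m * (g[k, -length(edges)] - g[k, -1]))
  f
}

# Invert the observed score covariance matrix to latent correlations,
# pair by pair, on a fine grid. For pairs of rare categories the moment
# curve g(rho) is nearly flat, so a plain inversion amplifies sampling
# noise into extreme correlations; instead each pair gets the
# smallest-magnitude rho whose implied covariance lies within one
# standard error of the observed one (parsimony under uncertainty).
# Informative pairs have tiny standard errors and are unaffected.
invert_score_cov <- function(V, H, n_obs) {
  K <- ncol(H); d <- nrow(V)
  fact <- factorial(seq_len(K))
  grid <- seq(-0.999, 0.999, by = 0.001)
  P <- outer(grid, seq_len(K), "^")
  ord <- order(abs(grid))          # candidates by increasing |rho|
  R <- diag(d)
  for (i in seq_len(d - 1)) for (j in seq((i + 1), d)) {
    v <- V[i, j]
    if (!is.finite(v)) next
    g <- as.vector(P %*% (H[i, ] * H[j, ] / fact))
    se <- 0.25 * sqrt(V[i, i] * V[j, j] / max(n_obs[i, j], 2))
    ok <- abs(g - v) <= se
    R[i, j] <- R[j, i] <- if (any(ok)) grid[ord[ok[ord]][1]]
                          else grid[which.min(abs(g - v))]
  }
  dimnames(R) <- dimnames(V)
  R
}

smoothed_probs <- function(counts, alpha) {
  p <- (counts + alpha) / (sum(counts) + alpha * length(counts))
  p / sum(p)
}

#' Fit the Gaussian-copula generator
#'
#' Estimates per-variable marginals with the missing state as its own
#' category (categoricals) or masking probability (numerics), transforms
#' every variable to normal scores (rank-based for numerics,
#' conditional-mean latent placement for categoricals), and estimates the
#' latent correlation from pairwise-complete score covariances with
#' polyserial-style de-attenuation and positive-definite repair.
#' The survival block stores OS time, OS/EFS event indicators and the
#' difference `delta = os - efs` computed rowwise where both are observed;
#' EFS time itself is never modeled directly.
#'
#' @param train Training [cohort_table()] (>= 30 rows, EFS/OS declared).
#' @param config Hyperparameters: `shrinkage` (latent correlation shrink
#'   toward identity, in `[0,1)`), `smoothing_bandwidth` (uniform jitter
#'   width on the copula scale at inversion time), `category_smoothing`
#'   (additive smoothing for category probabilities).
#' @param seed Integer seed (stochastic category placement).
#' @return A `generator_model`.
#' @export
fit_generator <- function(train,
                          config = list(shrinkage = 0,
                                        smoothing_bandwidth = 0,
                                        category_smoothing = 0.5),
                          seed = 1L) {
  if (train$n < 30) stop("need at least 30 training rows")
  ep <- train$schema$endpoints
  if (is.null(ep$efs) || is.null(ep$os))
    stop("schema must declare EFS and OS endpoint pairs")
  restore <- local_rng(seed)
  on.exit(restore())
  alpha <- if (is.null(config$category_smoothing)) 0.5
           else config$category_smoothing

  data <- train$data
  efs_t <- ep$efs[1]
  os_t <- ep$os[1]
  # the difference variable replaces EFS time inside the copula
  delta <- ifelse(!is.na(data[[os_t]]) & !is.na(data[[efs_t]]),
                  data[[os_t]] - data[[efs_t]], NA)

  marginals <- list()
  score_cols <- list()
  hermites <- list()      # score Hermite coefficients per latent column
  excluded <- character(0)

  add_continuous <- function(name, values) {
    obs <- values[!is.na(values)]
    p_miss <- mean(is.na(values))
    if (length(obs) == 0) return(NULL)
    list(kind = "continuous", values = sort(obs), p_missing = p_miss)
  }

  for (s in train$schema$specs) {
    if (s$name == efs_t) next
    v <- data[[s$name]]
    if (all(is.na(v))) {
      warning("variable '", s$name, "' entirely missing; excluded")
      excluded <- c(excluded, s$name)
      next
    }
    if (s$kind %in% c("continuous", "time")) {
      marginals[[s$name]] <- add_continuous(s$name, v)
      score_cols[[s$name]] <- variable_scores(v, s)
      hermites[[s$name]] <- NULL  # continuous: identity score, set below
      p_miss <- marginals[[s$name]]$p_missing
      if (p_miss > 0) {
        mask <- ifelse(is.na(v), "1", "0")
        pm <- c("0" = 1 - p_miss, "1" = p_miss)
        score_cols[[paste0(".miss_", s$name)]] <-
          variable_scores(mask, list(kind = "binary"), probs = pm)
        hermites[[paste0(".miss_", s$name)]] <- category_hermite_coefs(pm)
      }
    } else {
      # categories on their own latent; the missing state is factorized
      # into an independent mask dimension (same treatment as numerics),
      # so the trinary output (e.g. 0 / 1 / na) never distorts the
      # category thresholds
      p_miss <- mean(is.na(v))
      cats <- setdiff(s$categories, "na")
      counts <- vapply(cats, function(cc) sum(v == cc, na.rm = TRUE),
                       numeric(1))
      probs <- smoothed_probs(counts, alpha)
      marginals[[s$name]] <- list(kind = "categorical", categories = cats,
                                  probs = probs, p_missing = p_miss)
      sc <- variable_scores(v, s, probs = probs)
      sc[is.na(v)] <- NA_real_
      score_cols[[s$name]] <- sc
      hermites[[s$name]] <- category_hermite_coefs(probs)
      if (p_miss > 0) {
        mask <- ifelse(is.na(v), "1", "0")
        pm <- c("0" = 1 - p_miss, "1" = p_miss)
        score_cols[[paste0(".miss_", s$name)]] <-
          variable_scores(mask, list(kind = "binary"), probs = pm)
        hermites[[paste0(".miss_", s$name)]] <- category_hermite_coefs(pm)
      }
    }
  }
  # delta marginal (support >= 0 by the EFS <= OS invariant)
  marginals[[".delta"]] <- add_continuous(".delta", delta)
  if (is.null(marginals[[".delta"]]))
    stop("no rows with both EFS and OS observed")
  score_cols[[".delta"]] <- variable_scores(delta, list(kind = "continuous"))
  if (marginals[[".delta"]]$p_missing > 0) {
    mask <- ifelse(is.na(delta), "1", "0")
    pm <- c("0" = 1 - marginals[[".delta"]]$p_missing,
            "1" = marginals[[".delta"]]$p_missing)
    score_cols[[".miss_.delta"]] <-
      variable_scores(mask, list(kind = "binary"), probs = pm)
    hermites[[".miss_.delta"]] <- category_hermite_coefs(pm)
  }

  S <- do.call(cbind, score_cols)
  V <- suppressWarnings(stats::cov(S, use = "pairwise.complete.obs"))
  K <- 8L
  H <- matrix(0, ncol(S), K, dimnames = list(colnames(S), NULL))
  for (nm in colnames(S)) {
    H[nm, ] <- if (is.null(hermites[[nm]]))
      c(sqrt(max(V[nm, nm], 1e-8)), rep(0, K - 1))  # continuous: identity
    else hermites[[nm]]
  }
  n_pair <- crossprod(!is.na(S))
  R <- invert_score_cov(V, H, n_pair)
  diag(R) <- 1
  R <- nearest_correlation(R)

  structure(list(marginals = marginals,
                 latent_corr = R,
                 latent_names = colnames(S),
                 schema = train$schema,
                 excluded = excluded,
                 config = config,
                 fit_meta = list(n_train = train$n, seed = seed,
                                 timestamp = format(Sys.time(), tz = "UTC"))),
            class = "generator_model")
}

#' @export
print.generator_model <- function(x, ...) {
  cat("generator_model:", length(x$marginals), "marginals,",
      nrow(x$latent_corr), "latent dimensions, fit on n =",
      x$fit_meta$n_train, "\n")
  invisible(x)
}

# empirical quantile inversion bounded to the training support
invert_continuous <- function(u, sorted_values, bandwidth = 0) {
  if (bandwidth > 0) {
    u <- u + (stats::runif(length(u)) - 0.5) * bandwidth
    u <- pmin(pmax(u, 0), 1)
  }
  stats::quantile(sorted_values, probs = u, type = 7, names = FALSE)
}

#' Sample a synthetic cohort from a fitted generator
#'
#' Draws a latent multivariate normal with the (shrinkage-adjusted) fitted
#' correlation, inverts the empirical marginals (continuous values stay
#' inside the training support), applies the coupled missingness masks, and
#' reconstructs EFS from OS and the difference via [reconstruct_efs()].
#'
#' @param model A `generator_model` from [fit_generator()].
#' @param n Number of synthetic patients.
#' @param seed Integer seed.
#' @return A schema-valid [cohort_table()] labeled `"synthetic"`.
#' @export
sample_synthetic <- function(model, n, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  restore <- local_rng(seed)
  on.exit(restore())
  gamma <- if (is.null(model$config$shrinkage)) 0 else model$config$shrinkage
  bw <- if (is.null(model$config$smoothing_bandwidth)) 0
        else model$config$smoothing_bandwidth
  d <- length(model$latent_names)
  R <- (1 - gamma) * model$latent_corr + gamma * diag(d)
  Z <- matrix(stats::rnorm(n * d), n) %*% chol(R)
  colnames(Z) <- model$latent_names
  U <- stats::pnorm(Z)

  cols <- list()
  for (nm in names(model$marginals)) {
    marg <- model$marginals[[nm]]
    if (marg$kind == "continuous") {
      x <- invert_continuous(U[, nm], marg$values, bandwidth = bw)
      mask_col <- paste0(".miss_", nm)
      if (mask_col %in% colnames(U))
        x[U[, mask_col] > 1 - marg$p_missing] <- NA
      cols[[nm]] <- x
    } else {
      cum <- cumsum(marg$probs)
      idx <- findInterval(U[, nm], cum) + 1L
      idx[idx > length(marg$categories)] <- length(marg$categories)
      lab <- marg$categories[idx]
      mask_col <- paste0(".miss_", nm)
      if (mask_col %in% colnames(U) && marg$p_missing > 0)
        lab[U[, mask_col] > 1 - marg$p_missing] <- NA
      cols[[nm]] <- lab
    }
  }

  ep <- model$schema$endpoints
  os_t <- ep$os[1]; efs_t <- ep$efs[1]
  os_time <- round(cols[[os_t]], 1)
  delta <- cols[[".delta"]]
  efs_time <- round(reconstruct_efs(os_time, delta), 1)
  efs_time[is.na(os_time)] <- NA

  out <- list()
  for (s in model$schema$specs) {
    out[[s$name]] <-
      if (s$name == efs_t) efs_time
      else if (s$name == os_t) os_time
      else if (s$name %in% model$excluded) rep(NA, n)
      else cols[[s$name]]
  }
  cohort_table(as.data.frame(out, stringsAsFactors = FALSE,
                             check.names = FALSE),
               model$schema, label = "synthetic")
}

#' Serialize / load a generator model as JSON
#' @param model A `generator_model`.
#' @param path File path.
#' @export
write_generator <- function(model, path) {
  obj <- model
  obj$latent_corr <- unclass(obj$latent_corr)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' @rdname write_generator
#' @export
read_generator <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$latent_corr <- as.matrix(raw$latent_corr)
  dimnames(raw$latent_corr) <- list(raw$latent_names, raw$latent_names)
  raw$marginals <- lapply(raw$marginals, function(m) {
    if (m$kind == "categorical") m$probs <- stats::setNames(
      as.numeric(m$probs), m$categories)
    m
  })
  # rebuild the schema object
  specs <- lapply(seq_along(raw$schema$specs), function(i) {
    s <- raw$schema$specs[[i]]
    variable_spec(s$name, s$kind, units = if (is.null(s$units)) "" else
                  s$units, categories = s$categories,
                  missing_allowed = isTRUE(s$missing_allowed), pair = s$pair)
  })
  ep <- raw$schema$endpoints
  raw$schema <- cohort_schema(specs, cr = ep$cr, efs = ep$efs, os = ep$os)
  structure(raw, class = "generator_model")
}

#' Seeded random-search tuning of the generator
#'
#' The objective averages three holdout scores tied to the quantities the
#' study optimized for: regularized support coverage restricted to the CR
#' variable, the Kaplan-Meier divergence score for OS, and the basic
#' statistical measure restricted to the OS - EFS difference. Equal weights.
#'
#' @param train Training [cohort_table()].
#' @param holdout Non-empty holdout [cohort_table()].
#' @param budget Number of random-search trials (>= 1).
#' @param seed Integer seed; trial `i` of a larger budget with the same seed
#'   reproduces trial `i` of a smaller one.
#' @return A `tuning_result` with `best` hyperparameters, `best_objective`,
#'   and the per-trial `trace`.
#' @export
tune_generator <- function(train, holdout, budget = 10, seed = 1L) {
  stopifnot(budget >= 1)
  if (holdout$n < 1) stop("holdout is empty")
  trace <- data.frame(trial = integer(0), shrinkage = numeric(0),
                      smoothing_bandwidth = numeric(0),
                      category_smoothing = numeric(0), objective = numeric(0))
  best <- NULL
  for (i in seq_len(budget)) {
    restore <- local_rng(seed + 7919L * i)
    hp <- list(shrinkage = stats::runif(1, 0, 0.5),
               smoothing_bandwidth = stats::runif(1, 0, 0.05),
               category_smoothing = stats::runif(1, 0.1, 2))
    restore()
    model <- fit_generator(train, config = hp, seed = seed + 7919L * i + 1L)
    syn <- sample_synthetic(model, holdout$n, seed = seed + 7919L * i + 2L)
    obj <- tuning_objective(holdout, syn)
    trace <- rbind(trace, data.frame(trial = i, shrinkage = hp$shrinkage,
                                     smoothing_bandwidth =
                                       hp$smoothing_bandwidth,
                                     category_smoothing =
                                       hp$category_smoothing,
                                     objective = obj))
    if (is.null(best) || obj > best$objective)
      best <- list(hyperparameters = hp, objective = obj, trial = i)
  }
  structure(list(best = best$hyperparameters,
                 best_objective = best$objective,
                 best_trial = best$trial, trace = trace, seed = seed),
            class = "tuning_result")
}

# objective components: CR support coverage, OS KM divergence, delta BSM
tuning_objective <- function(holdout, syn) {
  ep <- holdout$schema$endpoints
  cr_var <- ep$cr
  rsc_cr <- rsc_variable(holdout$data[[cr_var]], syn$data[[cr_var]],
                         holdout$schema$specs[[cr_var]]$categories)
  km <- km_divergence_score(
    list(times = as.numeric(holdout$data[[ep$os[1]]]),
         events = as.integer(holdout$data[[ep$os[2]]] == "1")),
    list(times = as.numeric(syn$data[[ep$os[1]]]),
         events = as.integer(syn$data[[ep$os[2]]] == "1")))
  d_real <- holdout$data[[ep$os[1]]] - holdout$data[[ep$efs[1]]]
  d_syn <- syn$data[[ep$os[1]]] - syn$data[[ep$efs[1]]]
  bsm_d <- bsm_variable(d_real[!is.na(d_real)], d_syn[!is.na(d_syn)])
  mean(c(rsc_cr, km, bsm_d))
}
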