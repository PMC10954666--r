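# Normalized survival-fidelity scores: Kaplan-Meier divergence, optimism
# and short-sightedness, comparing a synthetic cohort's time-to-event
# behavior per endpoint with the original's. Curves are carried forward
# flat beyond their last observation (no extrapolation).

as_surv_input <- function(x) {
  if (inherits(x, "km_curve")) stop("pass raw (times, events), not a curve")
  times <- as.numeric(x$times)
  events <- as.integer(x$events)
  ok <- !is.na(times) & !is.na(events)
  list(times = times[ok], events = events[ok])
}

# mean absolute / signed difference between two KM step curves on [0, T]
km_curve_integral <- function(real, syn) {
  real <- as_surv_input(real); syn <- as_surv_input(syn)
  if (!length(real$times) || !length(syn$times)) stop("empty input")
  T_real <- max(real$times)
  if (T_real <= 0) stop("zero-length follow-up")
  cr <- km_estimate(real$times, real$events)
  cs <- km_estimate(syn$times, syn$events)
  grid <- sort(unique(c(0, cr$event_times, cs$event_times, T_real)))
  grid <- grid[grid <= T_real]
  widths <- diff(c(grid, T_real))
  sr <- km_surv_at(cr, grid)
  ss <- km_surv_at(cs, grid)
  list(d_abs = sum(widths * abs(sr - ss)) / T_real,
       d_signed = sum(widths * (ss - sr)) / T_real,
       horizon_real = T_real, horizon_syn = max(syn$times))
}

#' Kaplan-Meier divergence score
#'
#' `1 - D` where `D` is the time-averaged absolute difference between the
#' two survival curves over the original cohort's follow-up horizon,
#' integrated exactly over the union grid of step times.
#'
#' @param real,syn Lists with `times` and `events` for one endpoint.
#' @return Score in `[0, 1]`; 1 means identical curves.
#' @export
km_divergence_score <- function(real, syn) {
  1 - km_curve_integral(real, syn)$d_abs
}

#' Optimism score
#'
#' Signed time-averaged difference `O` of synthetic minus real survival
#' (positive = synthetic curve is optimistic); the normalized score is
#' `1 - |O|`.
#'
#' @inheritParams km_divergence_score
#' @return List with `signed_optimism` in `[-1, 1]` and `score` in `[0, 1]`.
#' @export
optimism_score <- function(real, syn) {
  o <- km_curve_integral(real, syn)$d_signed
  list(signed_optimism = o, score = 1 - abs(o))
}

#' Short-sightedness score
#'
#' Penalizes synthetic follow-up horizons shorter than the original's:
#' `1 - max(0, (T_real - T_syn) / T_real)` on the largest observed (event
#' or censoring) times. Overshooting the real horizon is not penalized.
#'
#' @inheritParams km_divergence_score
#' @return Score in `[0, 1]`.
#' @export
short_sightedness_score <- function(real, syn) {
  real <- as_surv_input(real); syn <- as_surv_input(syn)
  t_r <- max(real$times)
  if (t_r <= 0) stop("zero real horizon")
  1 - max(0, (t_r - max(syn$times)) / t_r)
}

endpoint_surv <- function(cohort, endpoint = c("os", "efs")) {
  endpoint <- match.arg(endpoint)
  ep <- cohort$schema$endpoints[[endpoint]]
  if (is.null(ep)) stop("endpoint '", endpoint, "' not declared")
  list(times = as.numeric(cohort$data[[ep[1]]]),
       events = as.integer(cohort$data[[ep[2]]] == "1"))
}

#' Survival-fidelity report for one endpoint
#'
#' @param real,syn [cohort_table()]s sharing one schema.
#' @param endpoint `"os"` or `"efs"`.
#' @return List with the three scores, the signed optimism, and both
#'   follow-up horizons (months).
#' @export
survival_fidelity_report <- function(real, syn, endpoint = c("os", "efs")) {
  endpoint <- match.arg(endpoint)
  r <- endpoint_surv(real, endpoint)
  s <- endpoint_surv(syn, endpoint)
  integ <- km_curve_integral(r, s)
  list(endpoint = toupper(endpoint),
       km_divergence_score = 1 - integ$d_abs,
       optimism_score = 1 - abs(integ$d_signed),
       signed_optimism = integ$d_signed,
       short_sightedness_score = short_sightedness_score(r, s),
       horizon_real = integ$horizon_real,
       horizon_syn = integ$horizon_syn)
}
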