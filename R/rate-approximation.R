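#' Restricted mean progression-free survival time under constant hazard
#'
#' For a constant total exit rate a = lambda_hi + lambda_hd out of the
#' healthy state, exit times are exponential and the restricted mean
#' progression-free survival time truncated at `tau` is
#' (1 - exp(-a * tau)) / a, with the continuous limit `tau` as a -> 0.
#'
#' @param total_exit Nonnegative total exit rate from health (per year).
#' @param tau Positive truncation time (years).
#' @return The restricted mean PFS time (years).
#' @examples
#' rmpfst(1.5725, 2.97)  # ~0.63
#' @export
rmpfst <- function(total_exit, tau) {
  if (any(tau <= 0)) stop("`tau` must be positive")
  if (any(total_exit < 0)) stop("`total_exit` must be nonnegative")
  x <- total_exit * tau
  ifelse(x < 1e-8, tau * (1 - x / 2 + x^2 / 6), (1 - exp(-x)) / total_exit)
}

#' Solve for the total exit rate from the PFS curve's restricted AUC
#'
#' Inverts the restricted-mean relation: finds the unique positive rate a
#' such that `rmpfst(a, tau_pfs)` equals the observed area under the PFS
#' curve.  The restricted mean is strictly decreasing in a, from `tau_pfs`
#' at a = 0 towards 0, so a root exists and is unique whenever
#' 0 < `auc_pfs` < `tau_pfs`.  Solved by Brent's method on a bracketing
#' interval whose upper end is doubled until it straddles the root.
#'
#' @param auc_pfs Restricted area under the PFS curve (years).
#' @param tau_pfs Maximum observation time of the PFS analysis (years).
#' @param tol Absolute tolerance on the root (default 1e-12).
#' @return The total exit rate lambda_hi + lambda_hd (per year).
#' @examples
#' solve_total_exit_rate(0.63, 2.97)  # ~1.572
#' @export
solve_total_exit_rate <- function(auc_pfs, tau_pfs, tol = 1e-12) {
  if (!is.finite(auc_pfs) || auc_pfs <= 0) stop("`auc_pfs` must be positive")
  if (auc_pfs >= tau_pfs)
    stop("no positive solution (AUC must be < tau)")
  f <- function(a) rmpfst(a, tau_pfs) - auc_pfs
  hi <- 1 / auc_pfs
  while (f(hi) > 0) hi <- hi * 2
  stats::uniroot(f, c(1e-12, hi), tol = tol)$root
}

#' Risk of death for healthy patients
#'
#' Approximates rho = lambda_hd / (lambda_hi + lambda_hd), the probability
#' that an exit from health is a direct death, as the fraction of PFS
#' events that occur simultaneously in the OS analysis.
#'
#' @param n_simul Number of simultaneous PFS/OS events.
#' @param n_pfs_events Total number of PFS events (> 0).
#' @return A probability in \[0, 1\].
#' @examples
#' estimate_rho(10, 17)
#' @export
estimate_rho <- function(n_simul, n_pfs_events) {
  if (n_pfs_events <= 0) stop("`n_pfs_events` must be positive")
  if (n_simul < 0 || n_simul > n_pfs_events)
    stop("`n_simul` must lie in [0, n_pfs_events]")
  n_simul / n_pfs_events
}

#' Split the total exit rate into its two components
#'
#' A transition out of health is a direct death with probability `rho`
#' and a progression with probability 1 - `rho`, so
#' lambda_hd = rho * total and lambda_hi = (1 - rho) * total.
#'
#' @param total_exit Nonnegative total exit rate (per year).
#' @param rho Probability in \[0, 1\].
#' @return Named numeric vector `c(lambda_hi = , lambda_hd = )`.
#' @export
split_exit_rate <- function(total_exit, rho) {
  if (rho < 0 || rho > 1) stop("`rho` must lie in [0, 1]")
  if (total_exit < 0) stop("`total_exit` must be nonnegative")
  c(lambda_hi = (1 - rho) * total_exit, lambda_hd = rho * total_exit)
}

#' Restricted mean overall survival time by inverse probability weighting
#'
#' Approximates the restricted mean OS time truncated at the maximum
#' observation time from event and censoring times:
#' (((Ne + Nc) / Ne) * sum(events) + sum(censorings)) / (Ne + Nc).
#' With no censoring this reduces exactly to the sample mean of the event
#' times.
#'
#' @param event_times Observed death times (years); at least one.
#' @param censor_times Right-censoring times (years); may be empty.
#' @return The restricted mean OS time (years).
#' @examples
#' rmost_ipw(c(1, 3), c(2, 2))  # 3.0
#' @export
rmost_ipw <- function(event_times, censor_times = numeric(0)) {
  ne <- length(event_times)
  nc <- length(censor_times)
  if (ne == 0L) stop("at least one event is required")
  if (nc == 0L) return(mean(event_times))  # exact uncensored collapse
  (((ne + nc) / ne) * sum(event_times) + sum(censor_times)) / (ne + nc)
}

#' Total person-time of observation from known times
#'
#' The sum of all event and censoring times: usable whenever censoring
#' times can be read off the curve.
#'
#' @inheritParams rmost_ipw
#' @return Total person-time (years).
#' @export
person_time_exact <- function(event_times, censor_times = numeric(0)) {
  sum(event_times) + sum(censor_times)
}

#' Total person-time of observation from summary data
#'
#' When censoring times are not denoted on the published curve, total
#' person-time is recovered from the summary alone by substituting the
#' inverse-probability-weighted restricted mean (for which the curve's
#' restricted AUC stands in) back into the person-time sum:
#' `E = AUC * (Ne + Nc) + sum(event times) * (1 - (Ne + Nc) / Ne)`.
#' The same formula applies to PFS summaries.
#'
#' @param summary A [survival_summary()].
#' @return Approximate total person-time (years).
#' @examples
#' os <- survival_summary("os", 44, 1, 24.17, 2.99, 0.62)
#' person_time_ipw(os)  # ~27.35
#' @export
person_time_ipw <- function(summary) {
  stopifnot(inherits(summary, "survival_summary"))
  ne <- summary$n_events
  nc <- summary$n_censored
  if (ne == 0L) stop("person-time approximation requires at least one event")
  summary$auc * (ne + nc) + summary$event_time_sum * (1 - (ne + nc) / ne)
}

#' Person-time of observation in the ill state
#'
#' The difference between total OS and total PFS person-time.  A
#' nonpositive difference is returned as-is; downstream estimates built on
#' it are flagged invalid rather than erroring, since heavily censored
#' analyses can make this approximation degenerate.
#'
#' @param e_os,e_pfs Total person-time (years) in the OS and PFS analyses.
#' @return E_ill = E_os - E_pfs (years).
#' @export
ill_person_time <- function(e_os, e_pfs) e_os - e_pfs

#' Number of ill-to-dead transitions
#'
#' Deaths not matched by a simultaneous PFS event must have occurred from
#' the ill state: N_id = N_os_events - N_simul.
#'
#' @param n_os_events Total OS events.
#' @param n_simul Simultaneous PFS/OS events.
#' @return Integer count.
#' @export
count_id_events <- function(n_os_events, n_simul) {
  if (n_simul < 0 || n_simul > n_os_events)
    stop("`n_simul` must lie in [0, n_os_events]")
  as.integer(n_os_events - n_simul)
}

#' Ill-to-dead transition rate
#'
#' Occurrence/exposure estimate: events in the ill state divided by
#' person-time in the ill state.  When `e_ill` is nonpositive the estimate
#' is still returned (it may be negative or infinite) together with an
#' invalidity flag, so that simulation aggregates can include degenerate
#' replications.
#'
#' @param n_id Number of ill-to-dead transitions.
#' @param e_ill Person-time in the ill state (years).
#' @return A list with `lambda_id` and logical `valid`.
#' @export
estimate_lambda_id <- function(n_id, e_ill) {
  list(lambda_id = n_id / e_ill, valid = e_ill > 0 && n_id > 0)
}

#' Bundle of transition rates for the illness-death model
#'
#' @param lambda_hi,lambda_hd,lambda_id Transition rates (per year) for
#'   healthy-to-ill, healthy-to-dead and ill-to-dead.
#' @return An object of class `transition_rates` with the three rates plus
#'   the derived `total_exit` (= lambda_hi + lambda_hd) and
#'   `rho` (= lambda_hd / total_exit).
#' @export
transition_rates <- function(lambda_hi, lambda_hd, lambda_id) {
  total <- lambda_hi + lambda_hd
  structure(
    list(lambda_hi = lambda_hi, lambda_hd = lambda_hd,
         lambda_id = lambda_id, total_exit = total,
         rho = if (total > 0) lambda_hd / total else NA_real_),
    class = "transition_rates")
}

#' @export
print.transition_rates <- function(x, digits = 4, ...) {
  cat(sprintf(
    paste0("Illness-death transition rates (per year):\n",
           "  healthy -> ill  (lambda_hi): %.*g\n",
           "  healthy -> dead (lambda_hd): %.*g\n",
           "  ill -> dead     (lambda_id): %.*g\n",
           "  total exit from health: %.*g;  rho = %.*g\n"),
    digits, x$lambda_hi, digits, x$lambda_hd, digits, x$lambda_id,
    digits, x$total_exit, digits, x$rho))
  invisible(x)
}

#' Approximate transition rates from PFS and OS summary data
#'
#' The end-to-end approximation: solve the restricted-mean relation for
#' the total exit rate from health, split it using the simultaneous-event
#' fraction, approximate person-time in the ill state from the two
#' analyses' person-times, and estimate the ill-to-dead rate as events per
#' person-time.
#'
#' @param pfs,os [survival_summary()] objects for the PFS and OS analyses.
#' @param n_simul Number of simultaneous PFS/OS events.
#' @param person_time `"ipw"` (default) approximates person-time from the
#'   summaries alone; `"exact"` uses summed event + censoring times and
#'   requires summaries carrying `censor_time_sum` (e.g. built from
#'   individual records by [summarize_survival_analysis()]).
#'
#' @return A list with components `rates` (a [transition_rates()] object)
#'   and `diagnostics`: person-times `e_os`, `e_pfs`, `e_ill`, the
#'   ill-to-dead event count `n_id`, the fitted restricted means `rmpfst`
#'   and `rmost`, and logical `valid` (`FALSE` when `e_ill <= 0` or
#'   `n_id <= 0` makes the lambda_id estimate degenerate).
#' @examples
#' pfs <- survival_summary("pfs", 17, 5, 7.02, 2.97, 0.63)
#' os  <- survival_summary("os", 44, 1, 24.17, 2.99, 0.62)
#' approximate_rates(pfs, os, n_simul = 10)$rates
#' @export
approximate_rates <- function(pfs, os, n_simul,
                              person_time = c("ipw", "exact")) {
  stopifnot(inherits(pfs, "survival_summary"), inherits(os, "survival_summary"))
  person_time <- match.arg(person_time)
  if (n_simul > min(pfs$n_events, os$n_events))
    stop("`n_simul` cannot exceed the event count of either analysis")

  total <- solve_total_exit_rate(pfs$auc, pfs$tau)
  rho <- estimate_rho(n_simul, pfs$n_events)
  split <- split_exit_rate(total, rho)

  if (person_time == "exact") {
    if (is.na(pfs$censor_time_sum) || is.na(os$censor_time_sum))
      stop("exact person-time requires summaries with known censoring times")
    e_os <- os$event_time_sum + os$censor_time_sum
    e_pfs <- pfs$event_time_sum + pfs$censor_time_sum
  } else {
    e_os <- person_time_ipw(os)
    e_pfs <- person_time_ipw(pfs)
  }
  e_ill <- ill_person_time(e_os, e_pfs)
  n_id <- count_id_events(os$n_events, n_simul)
  lid <- estimate_lambda_id(n_id, e_ill)

  list(
    rates = transition_rates(split[["lambda_hi"]], split[["lambda_hd"]],
                             lid$lambda_id),
    diagnostics = list(
      e_os = e_os, e_pfs = e_pfs, e_ill = e_ill, n_id = n_id,
      rmpfst = rmpfst(total, pfs$tau), rmost = os$auc,
      valid = lid$valid))
}

#' Between-arm ratios of transition rates
#'
#' Elementwise hazard ratios lambda(arm a) / lambda(arm b) for the three
#' transitions, plus the relative risk of death for healthy patients,
#' rho(a) / rho(b).
#'
#' @param arm_a,arm_b [transition_rates()] objects; `arm_b` is the
#'   reference arm.
#' @return Named numeric vector with `lambda_hi`, `lambda_hd`, `lambda_id`
#'   hazard ratios and `rho_rr`.
#' @export
rate_ratios <- function(arm_a, arm_b) {
  stopifnot(inherits(arm_a, "transition_rates"),
            inherits(arm_b, "transition_rates"))
  denom <- c(arm_b$lambda_hi, arm_b$lambda_hd, arm_b$lambda_id, arm_b$rho)
  if (any(!is.finite(denom)) || any(denom == 0))
    stop("reference-arm rates must be positive and finite")
  c(lambda_hi = arm_a$lambda_hi / arm_b$lambda_hi,
    lambda_hd = arm_a$lambda_hd / arm_b$lambda_hd,
    lambda_id = arm_a$lambda_id / arm_b$lambda_id,
    rho_rr = arm_a$rho / arm_b$rho)
}
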