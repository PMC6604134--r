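#' State-occupancy fractions of the progressive illness-death model
#'
#' Closed-form occupancy probabilities for the three-state
#' healthy/ill/dead process with constant rates.  Starting healthy,
#' P(healthy at t) = exp(-a t) with a = lambda_hi + lambda_hd, and
#' P(ill at t) = lambda_hi (exp(-a t) - exp(-lambda_id t)) / (lambda_id - a),
#' with the removable singularity at lambda_id = a handled by its limit
#' lambda_hi t exp(-a t).  Starting ill, P(ill at t) = exp(-lambda_id t).
#' A cohort's fractions are the mixture weighted by its baseline
#' composition; any baseline remainder is dead.
#'
#' @param rates A [transition_rates()] object (all rates >= 0).
#' @param baseline_mix Length-2 numeric, fractions (healthy, ill) at t = 0;
#'   must be nonnegative and sum to at most 1.
#' @param times Nonnegative evaluation times (years).  Default: 1000
#'   uniform points on \[0, `horizon`\].
#' @param horizon Upper end of the default grid (years).
#'
#' @return An object of class `occupancy_fractions`: a data frame with
#'   columns `time`, `p_healthy`, `p_ill`, `p_dead` and attribute
#'   `baseline_mix`.  Rows sum to 1.
#' @examples
#' r <- transition_rates(0.33, 0.53, 3.28)
#' occ <- occupancy_fractions(r, times = seq(0, 5, 0.01))
#' head(occ)
#' @export
occupancy_fractions <- function(rates, baseline_mix = c(1, 0), times = NULL,
                                horizon = 5) {
  stopifnot(inherits(rates, "transition_rates"))
  if (any(c(rates$lambda_hi, rates$lambda_hd, rates$lambda_id) < 0))
    stop("rates must be nonnegative")
  if (length(baseline_mix) != 2L || any(baseline_mix < 0) ||
      sum(baseline_mix) > 1 + 1e-12)
    stop("`baseline_mix` must be two nonnegative fractions summing to <= 1")
  if (is.null(times)) times <- seq(0, horizon, length.out = 1000L)
  if (any(times < 0)) stop("`times` must be nonnegative")

  w_h <- baseline_mix[1]
  w_i <- baseline_mix[2]
  a <- rates$total_exit
  lid <- rates$lambda_id

  surv_h <- exp(-a * times)
  surv_i <- exp(-lid * times)
  # P(ill at t | healthy at 0); series/limit branch at lid == a
  if (abs(lid - a) < 1e-9 * max(lid, a, 1)) {
    p_ih <- rates$lambda_hi * times * surv_h
  } else {
    p_ih <- rates$lambda_hi * (surv_h - surv_i) / (lid - a)
  }
  p_healthy <- w_h * surv_h
  p_ill <- w_h * p_ih + w_i * surv_i
  out <- data.frame(time = times, p_healthy = p_healthy, p_ill = p_ill,
                    p_dead = 1 - p_healthy - p_ill)
  attr(out, "baseline_mix") <- c(healthy = w_h, ill = w_i)
  class(out) <- c("occupancy_fractions", "data.frame")
  out
}

#' Partitioned-survival curves implied by occupancy fractions
#'
#' The model's PFS curve is the healthy fraction and its OS curve the
#' alive (healthy + ill) fraction, so that OS(t) - PFS(t) equals the ill
#' fraction pointwise — the identity partitioned-survival modelling
#' exploits in reverse.
#'
#' @param fractions An [occupancy_fractions()] result.
#' @return A data frame with columns `time`, `pfs`, `os`.
#' @export
partitioned_curves <- function(fractions) {
  stopifnot(inherits(fractions, "occupancy_fractions"))
  data.frame(time = fractions$time,
             pfs = fractions$p_healthy,
             os = fractions$p_healthy + fractions$p_ill)
}

#' Expected quality-adjusted life-years over a horizon
#'
#' Trapezoidal integral of u_h * p_healthy(t) + u_i * p_ill(t) from 0 to
#' `horizon` on the fractions' time grid (the grid must reach `horizon`;
#' a grid point is interpolated at `horizon` if needed).  With both
#' utilities 1 this is the model's restricted mean OS time; with
#' u_h = 1, u_i = 0 it is the restricted mean PFS time.
#'
#' @param fractions An [occupancy_fractions()] result.
#' @param utility_healthy,utility_ill Utility weights in \[0, 1\].
#' @param horizon Positive integration horizon (years).
#' @return Expected QALYs (quality-adjusted years).
#' @export
expected_qalys <- function(fractions, utility_healthy, utility_ill, horizon) {
  stopifnot(inherits(fractions, "occupancy_fractions"))
  if (utility_healthy < 0 || utility_healthy > 1 ||
      utility_ill < 0 || utility_ill > 1)
    stop("utilities must lie in [0, 1]")
  if (horizon <= 0) stop("`horizon` must be positive")
  if (max(fractions$time) < horizon)
    stop("fractions grid does not reach `horizon`")
  q <- utility_healthy * fractions$p_healthy + utility_ill * fractions$p_ill
  t <- fractions$time
  keep <- t <= horizon
  tt <- t[keep]; qq <- q[keep]
  if (max(tt) < horizon) {
    tt <- c(tt, horizon)
    qq <- c(qq, stats::approx(t, q, xout = horizon)$y)
  }
  sum(diff(tt) * (utils::head(qq, -1) + utils::tail(qq, -1)) / 2)
}
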