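# Independent oracles used across the suite.

# Product-limit survival via the survival package (independent of km_estimate)
survfit_oracle <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  list(time = fit$time[fit$n.event > 0], surv = fit$surv[fit$n.event > 0])
}

# Restricted mean survival time via survival's own rmean machinery
survfit_rmst <- function(time, event, tau) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  unname(summary(fit, rmean = tau)$table["rmean"])
}

# Brute-force maximal matching between two multisets with |p - o| <= tol,
# by exhaustive recursion (exponential; tiny instances only)
match_oracle <- function(p, o, tol) {
  if (length(p) == 0L || length(o) == 0L) return(0L)
  best <- match_oracle(p[-1], o, tol)  # leave p[1] unmatched
  for (j in seq_along(o)) {
    if (abs(p[1] - o[j]) <= tol) {
      best <- max(best, 1L + match_oracle(p[-1], o[-j], tol))
    }
  }
  best
}

# Occupancy probabilities via matrix exponential of the generator
expm_occupancy <- function(rates, baseline_mix, t) {
  Q <- matrix(c(-(rates$lambda_hi + rates$lambda_hd), rates$lambda_hi, rates$lambda_hd,
                0, -rates$lambda_id, rates$lambda_id,
                0, 0, 0), nrow = 3, byrow = TRUE)
  p0 <- c(baseline_mix[1], baseline_mix[2], 1 - sum(baseline_mix))
  as.numeric(p0 %*% as.matrix(Matrix::expm(Q * t)))
}

# Closed-form solve of the restricted-mean relation via the Lambert W
# function (principal branch): a = 1/AUC + W0(-(tau/AUC) e^(-tau/AUC))/tau
lambertw_exit_rate <- function(auc, tau) {
  z <- -(tau / auc) * exp(-tau / auc)
  1 / auc + pracma::lambertWp(z) / tau
}

# Table of the packaged MESCC abstracted summaries, for direct arithmetic
mescc_arms <- function() {
  jsonlite::read_json(mescc_config_path(), simplifyVector = TRUE)$arms
}
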