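#' Kaplan-Meier product-limit estimate
#'
#' Computes the Kaplan-Meier estimate of the survival function from
#' right-censored event times.  Ties between events and censorings at the
#' same time are resolved events-first (the standard convention: a patient
#' censored at time t is still at risk for an event at t).
#'
#' @param time Numeric vector of nonnegative observation times (years).
#' @param event Logical or 0/1 vector; `TRUE`/1 for an observed event,
#'   `FALSE`/0 for right censoring.
#'
#' @return An object of class `km_curve`: a list with components
#'   `time` (distinct event times, strictly increasing), `surv`
#'   (survival fraction just after each event time; right-continuous step
#'   function equal to 1 before the first event), `n_risk`, `n_event`
#'   (at-risk and event counts at each step) and `max_time` (the largest
#'   observation time, event or censoring, up to which the curve is defined).
#'
#' @examples
#' km_estimate(c(1, 3, 0.5), c(1, 1, 0))
#' @export
km_estimate <- function(time, event) {
  event <- as.logical(event)
  if (length(time) == 0L) stop("at least one observation is required")
  if (length(event) != length(time)) stop("`time` and `event` lengths differ")
  if (anyNA(time) || anyNA(event)) stop("missing values in `time` or `event`")
  if (any(time < 0)) stop("negative observation times are not allowed")

  tev <- sort(unique(time[event]))
  if (length(tev) == 0L) {
    return(structure(
      list(time = numeric(0), surv = numeric(0), n_risk = integer(0),
           n_event = integer(0), max_time = max(time)),
      class = "km_curve"))
  }
  # events-first tie rule: censored-at-t patients count as at risk at t
  s <- sort(time)
  n_risk <- length(time) - findInterval(tev, s, left.open = TRUE)
  n_event <- rle(sort(time[event]))$lengths  # aligned with tev (sorted unique)
  surv <- cumprod(1 - n_event / n_risk)
  structure(
    list(time = tev, surv = surv, n_risk = as.integer(n_risk),
         n_event = as.integer(n_event), max_time = max(time)),
    class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", length(x$time), "event time(s), max observation",
      format(x$max_time), "\n")
  if (length(x$time) > 0)
    print(data.frame(time = x$time, n_risk = x$n_risk,
                     n_event = x$n_event, surv = x$surv), ...)
  invisible(x)
}

#' Restricted area under a Kaplan-Meier curve
#'
#' Sums the area under each step of the curve from 0 up to the truncation
#' time `tau`.  This equals the restricted mean survival time of the
#' estimated distribution.  Beyond its last event time the curve is
#' extended as a constant at its final survival fraction.
#'
#' @param curve A [km_estimate()] result (`km_curve`).
#' @param tau Positive truncation time (years).
#'
#' @return The restricted AUC in years, a value in (0, `tau`].
#' @examples
#' km <- km_estimate(c(1, 3), c(1, 1))
#' restricted_auc(km, 3)  # 1*1.0 + 2*0.5 = 2.0
#' @export
restricted_auc <- function(curve, tau) {
  stopifnot(inherits(curve, "km_curve"))
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0)
    stop("`tau` must be a single positive time")
  # heights on [t_{k-1}, t_k): S(t_{k-1}); S = 1 before the first event
  lower <- c(0, curve$time)
  upper <- c(curve$time, Inf)
  height <- c(1, curve$surv)
  width <- pmax(0, pmin(upper, tau) - pmin(lower, tau))
  sum(width * height)
}

#' Count simultaneous PFS/OS events
#'
#' Events appearing at (numerically) the same time in the PFS and OS
#' analyses indicate direct healthy-to-dead transitions.  The count is the
#' size of a maximal one-to-one matching between the two multisets of event
#' times in which matched times differ by at most `tol`; each time is
#' consumed by at most one match.
#'
#' @param pfs_event_times,os_event_times Numeric vectors of event times.
#' @param tol Nonnegative matching tolerance (years).  The default 0 suits
#'   exact simulated or reconstructed times; a positive value accommodates
#'   digitization noise.
#'
#' @return Integer count of matched (simultaneous) events.
#' @examples
#' count_simultaneous_events(c(1, 2), c(1, 3))        # 1
#' count_simultaneous_events(c(1, 1), 1)              # 1
#' @export
count_simultaneous_events <- function(pfs_event_times, os_event_times,
                                      tol = 0) {
  if (!is.numeric(tol) || length(tol) != 1L || is.na(tol) || tol < 0)
    stop("`tol` must be a single nonnegative number")
  p <- sort(pfs_event_times)
  o <- sort(os_event_times)
  # greedy two-pointer sweep; maximal for interval (|p-o| <= tol) matching
  i <- 1L; j <- 1L; n <- 0L
  while (i <= length(p) && j <= length(o)) {
    d <- p[i] - o[j]
    if (abs(d) <= tol) {
      n <- n + 1L; i <- i + 1L; j <- j + 1L
    } else if (d > tol) {
      j <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  n
}

#' Summarize a survival analysis for rate approximation
#'
#' Assembles from individual observation records the sextuple of summary
#' quantities the approximation pipeline consumes: event count, censoring
#' count, summed event times, maximum observation time, and the restricted
#' area under the Kaplan-Meier curve truncated at that maximum.
#'
#' @inheritParams km_estimate
#' @param label Analysis label, `"pfs"` or `"os"`.
#'
#' @return An object of class `survival_summary`: a list with components
#'   `label`, `n_events`, `n_censored`, `event_time_sum`, `tau`, `auc`, and
#'   `censor_time_sum` (the summed censoring times, retained so that exact
#'   person-time can be used downstream when records are available; `NA`
#'   for summaries abstracted from publications).
#' @seealso [survival_summary()] to construct one directly from published
#'   values, [approximate_rates()].
#' @examples
#' summarize_survival_analysis(c(1, 2, 0.5), c(1, 1, 0), label = "os")
#' @export
summarize_survival_analysis <- function(time, event, label = c("pfs", "os")) {
  label <- match.arg(label)
  event <- as.logical(event)
  if (length(time) == 0L) stop("at least one observation is required")
  km <- km_estimate(time, event)
  tau <- max(time)
  survival_summary(
    label = label,
    n_events = sum(event),
    n_censored = sum(!event),
    event_time_sum = sum(time[event]),
    tau = tau,
    auc = restricted_auc(km, tau),
    censor_time_sum = if (any(!event)) sum(time[!event]) else 0)
}

#' Construct a survival-analysis summary from abstracted values
#'
#' The six quantities abstracted from a published Kaplan-Meier analysis.
#' Event and censoring counts come from the text or at-risk table; the
#' summed event times, maximum observation time, and restricted AUC come
#' from the digitized (or otherwise reconstructed) curve.
#'
#' @param label `"pfs"` or `"os"`.
#' @param n_events,n_censored Nonnegative counts.
#' @param event_time_sum Sum of observed event times (years).
#' @param tau Maximum observation time, event or censoring (years).
#' @param auc Restricted area under the curve up to `tau` (years).
#' @param censor_time_sum Sum of censoring times (years) when known;
#'   `NA` (the default) when censoring times cannot be read off the curve.
#'
#' @return A `survival_summary` object.
#' @export
survival_summary <- function(label, n_events, n_censored, event_time_sum,
                             tau, auc, censor_time_sum = NA_real_) {
  label <- match.arg(label, c("pfs", "os"))
  stopifnot(n_events >= 0, n_censored >= 0)
  if (n_events + n_censored > 0) {
    if (!(auc > 0 && auc <= tau))
      stop("`auc` must lie in (0, tau] for a nonempty analysis")
    if (event_time_sum > n_events * tau + 1e-9)
      stop("`event_time_sum` exceeds n_events * tau")
  }
  structure(
    list(label = label, n_events = as.integer(n_events),
         n_censored = as.integer(n_censored),
         event_time_sum = event_time_sum, tau = tau, auc = auc,
         censor_time_sum = censor_time_sum),
    class = "survival_summary")
}

#' @export
print.survival_summary <- function(x, ...) {
  cat(sprintf(
    "%s summary: %d events, %d censored, sum(event times) = %.4g y, tau = %.4g y, AUC = %.4g y\n",
    toupper(x$label), x$n_events, x$n_censored, x$event_time_sum, x$tau, x$auc))
  invisible(x)
}

#' Read individual patient data from CSV
#'
#' Expects columns `patient_id`, `time` (years), `event` (1 = event,
#' 0 = censored) and `analysis` (`"pfs"` or `"os"`).
#'
#' @param path Path to the CSV file.
#' @return A data frame with those four columns.
#' @export
read_ipd_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time", "event", "analysis")
  if (!all(need %in% names(d)))
    stop("IPD CSV must have columns: ", paste(need, collapse = ", "))
  d$analysis <- tolower(d$analysis)
  if (!all(d$analysis %in% c("pfs", "os")))
    stop("`analysis` must be 'pfs' or 'os'")
  if (!all(d$event %in% c(0, 1))) stop("`event` must be 0 or 1")
  d[need]
}

#' Read or write a survival summary as JSON
#'
#' JSON object with keys `label`, `n_events`, `n_censored`,
#' `event_time_sum`, `tau`, `auc` (and optionally `censor_time_sum`).
#'
#' @param path File path.
#' @return `read_summary_json()` returns a `survival_summary`.
#' @export
read_summary_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  survival_summary(
    label = x$label, n_events = x$n_events, n_censored = x$n_censored,
    event_time_sum = x$event_time_sum, tau = x$tau, auc = x$auc,
    censor_time_sum = if (is.null(x$censor_time_sum)) NA_real_
                      else x$censor_time_sum)
}

#' @param summary A `survival_summary`.
#' @rdname read_summary_json
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "survival_summary"))
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
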