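test_that("rmpfst evaluates the exponential restricted mean and its limits", {
  expect_equal(rmpfst(0, 2.97), 2.97)              # zero-rate limit
  expect_equal(rmpfst(1e-12, 2.97), 2.97, tolerance = 1e-9)
  expect_equal(rmpfst(1.5725, 2.97), 0.6299719, tolerance = 1e-6)
  expect_lt(rmpfst(1e6, 2.97), 1e-5)               # instantaneous exit
  expect_error(rmpfst(1, 0), "positive")
})

test_that("solve_total_exit_rate inverts the restricted-mean relation", {
  # frozen bisection-oracle values for the two case-study arms
  expect_equal(solve_total_exit_rate(0.63, 2.97), 1.572427, tolerance = 1e-5)
  expect_equal(solve_total_exit_rate(1.16, 5.25), 0.8522427, tolerance = 1e-5)
  # plug-in self-consistency: AUC = tau (1 - 1/e) at a = 1/tau
  tau <- 3.7
  expect_equal(solve_total_exit_rate(tau * (1 - exp(-1)), tau), 1 / tau,
               tolerance = 1e-9)
  expect_error(solve_total_exit_rate(3, 2.97), "no positive solution")
  expect_error(solve_total_exit_rate(-1, 2.97), "positive")
})

test_that("solve/evaluate round trip holds and the solve is monotone", {
  set.seed(101)
  for (i in 1:50) {
    tau <- stats::runif(1, 0.2, 20)
    auc <- stats::runif(1, 0.02, 0.98) * tau
    a <- solve_total_exit_rate(auc, tau)
    expect_equal(rmpfst(a, tau), auc, tolerance = 1e-9)
  }
  # strictly decreasing in the AUC at fixed tau
  tau <- 4.2
  aucs <- seq(0.1, 0.9, by = 0.05) * tau
  roots <- vapply(aucs, solve_total_exit_rate, numeric(1), tau_pfs = tau)
  expect_true(all(diff(roots) < 0))
})

test_that("the numerical root matches the Lambert-W closed form", {
  skip_if_not_installed("pracma")
  taus <- seq(0.5, 10, length.out = 20)
  for (tau in taus) {
    auc <- 0.37 * tau
    expect_equal(solve_total_exit_rate(auc, tau),
                 lambertw_exit_rate(auc, tau), tolerance = 1e-8)
  }
})

test_that("estimate_rho and split_exit_rate follow the exit decomposition", {
  expect_equal(estimate_rho(10, 17), 10 / 17)
  expect_equal(estimate_rho(19, 31), 19 / 31)
  expect_equal(estimate_rho(0, 5), 0)
  expect_error(estimate_rho(3, 0), "positive")
  expect_error(estimate_rho(6, 5), "n_pfs_events")

  s <- split_exit_rate(1.5725, 10 / 17)
  expect_equal(unname(sum(s)), 1.5725)           # exact reconstruction
  expect_equal(unname(s), c((7 / 17) * 1.5725, (10 / 17) * 1.5725))
  expect_equal(split_exit_rate(2, 0), c(lambda_hi = 2, lambda_hd = 0))
  expect_equal(split_exit_rate(2, 1), c(lambda_hi = 0, lambda_hd = 2))
  expect_error(split_exit_rate(1, 1.2), "rho")
})

test_that("rmost_ipw matches its defining formula and the uncensored mean", {
  expect_equal(rmost_ipw(c(1, 2, 3)), 2.0)                  # sample mean
  expect_equal(rmost_ipw(2, 1), ((2 / 1) * 2 + 1) / 2)      # 2.5
  expect_equal(rmost_ipw(c(1, 3), c(2, 2)), ((4 / 2) * 4 + 4) / 4)  # 3.0
  expect_error(rmost_ipw(numeric(0), c(1)), "at least one event")
  set.seed(7)
  x <- stats::rexp(40)
  expect_identical(rmost_ipw(x), mean(x))  # exact collapse, no censoring
})

test_that("person-time formulas agree with hand evaluations", {
  expect_equal(person_time_exact(c(1, 2), 0.5), 3.5)
  expect_equal(person_time_exact(numeric(0)), 0)

  os <- survival_summary("os", 44, 1, 24.17, 2.99, 0.62)
  pfs <- survival_summary("pfs", 17, 5, 7.02, 2.97, 0.63)
  expect_equal(person_time_ipw(os), 27.35068, tolerance = 1e-6)
  expect_equal(person_time_ipw(pfs), 11.79529, tolerance = 1e-6)
  expect_equal(ill_person_time(27.35068, 11.79529), 15.55539,
               tolerance = 1e-5)
  expect_equal(ill_person_time(44.64733, 37.65161), 6.99572,
               tolerance = 1e-5)

  # censoring-free collapse: IPW person-time equals the exact sum
  x <- c(0.4, 1.1, 2.5, 0.9)
  s <- summarize_survival_analysis(x, rep(1, 4), "os")
  expect_equal(person_time_ipw(s), person_time_exact(x), tolerance = 1e-12)
})

test_that("ill-state event count and rate behave, including degenerate cases", {
  expect_equal(count_id_events(44, 10), 34L)
  expect_equal(count_id_events(45, 19), 26L)
  expect_equal(count_id_events(7, 7), 0L)
  expect_error(count_id_events(5, 6), "n_simul")

  expect_equal(estimate_lambda_id(34, 15.55539)$lambda_id, 2.185738,
               tolerance = 1e-5)
  expect_equal(estimate_lambda_id(26, 6.99572)$lambda_id, 3.716558,
               tolerance = 1e-5)
  expect_false(estimate_lambda_id(0, 3)$valid)
  expect_false(estimate_lambda_id(5, -1)$valid)   # flagged, not an error
  expect_true(estimate_lambda_id(5, 2)$valid)
})

test_that("transition_rates derives total exit and rho consistently", {
  r <- transition_rates(0.33, 0.53, 3.28)
  expect_equal(r$total_exit, 0.86)
  expect_equal(r$rho, 0.53 / 0.86)
  expect_output(print(r), "lambda_hi")
})

test_that("approximate_rates composes the pipeline on the case-study arms", {
  pfs <- survival_summary("pfs", 17, 5, 7.02, 2.97, 0.63)
  os <- survival_summary("os", 44, 1, 24.17, 2.99, 0.62)
  fit <- approximate_rates(pfs, os, n_simul = 10)
  expect_equal(round(fit$rates$lambda_hi, 2), 0.65)
  expect_equal(round(fit$rates$lambda_hd, 2), 0.92)
  expect_equal(round(fit$rates$lambda_id, 2), 2.19)
  expect_equal(fit$diagnostics$n_id, 34L)
  expect_equal(fit$diagnostics$e_ill,
               fit$diagnostics$e_os - fit$diagnostics$e_pfs,
               tolerance = 1e-12)
  expect_true(fit$diagnostics$valid)
  expect_error(approximate_rates(pfs, os, n_simul = 20), "n_simul")

  # exact person-time route requires known censoring times
  expect_error(approximate_rates(pfs, os, 10, person_time = "exact"),
               "censoring times")
})

test_that("exact and IPW person-time routes coincide without censoring", {
  set.seed(55)
  cfg <- cohort_config(n_total = 200, n_healthy = 150,
                       rates = transition_rates(0.4, 0.5, 2))
  ipd <- simulate_cohort(cfg)
  h <- ipd$baseline == "healthy"
  pfs <- summarize_survival_analysis(ipd$pfs_time[h], ipd$pfs_event[h], "pfs")
  os <- summarize_survival_analysis(ipd$os_time, ipd$os_event, "os")
  ns <- count_simultaneous_events(ipd$pfs_time[h][ipd$pfs_event[h] == 1],
                                  ipd$os_time[ipd$os_event == 1])
  a <- approximate_rates(pfs, os, ns, person_time = "ipw")
  b <- approximate_rates(pfs, os, ns, person_time = "exact")
  expect_equal(a$rates$lambda_id, b$rates$lambda_id, tolerance = 1e-10)
})

test_that("rate_ratios returns elementwise ratios against the reference arm", {
  a <- transition_rates(0.3299004, 0.5223423, 3.716558)
  b <- transition_rates(0.6474698, 0.9249568, 2.185738)
  hr <- rate_ratios(a, b)
  expect_equal(round(hr[["lambda_hi"]], 2), 0.51)
  expect_equal(round(hr[["lambda_hd"]], 2), 0.56)
  expect_equal(unname(rate_ratios(a, a)), rep(1, 4))
  expect_error(rate_ratios(a, transition_rates(0, 1, 1)), "positive")
})
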