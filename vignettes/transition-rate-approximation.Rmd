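---
title: "Approximating illness-death transition rates from published survival analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Approximating illness-death transition rates from published survival analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(km2rates)
```

## The problem

Health-economic and counselling applications of quality-adjusted
life-years (QALYs) need *state-membership fractions*: the probability
that a patient is healthy, ill, or dead at each time $t$.  When a study
reports only progression-free survival (PFS) and overall survival (OS)
curves, the usual route is partitioned-survival modelling —
$p_\mathrm{healthy}(t) = \mathrm{PFS}(t)$,
$p_\mathrm{ill}(t) = \mathrm{OS}(t) - \mathrm{PFS}(t)$ — which cannot be
extrapolated beyond the observation window and is tied to the study
cohort's baseline mix.  State-transition modelling avoids both
limitations but needs the transition rates of the underlying multistate
process, which published PFS/OS analyses do not report.

`km2rates` implements an approximation that recovers those rates for the
**progressive, time-homogeneous, three-state Markov illness-death
model**: states healthy ($h$), ill ($i$), dead ($d$); constant rates
$\lambda_{hi}$, $\lambda_{hd}$, $\lambda_{id}$; no recovery transitions.
All three model assumptions are substantive: the method is inapplicable
when rates vary with time, depend on history, or when patients can
return to health.

## The approximation

The inputs are six quantities per analysis, all abstractable from a
published article plus a digitized (or otherwise reconstructed) version
of its Kaplan–Meier curves: event count $N^e$, censoring count $N^c$,
the sum of event times, the maximum observation time $\tau$, and the
restricted area under the KM curve up to $\tau$ (computed by summing the
area under each step), together with the number $N_\mathrm{simul}$ of
event times that appear simultaneously in both the PFS and OS analyses.

1. **Total exit rate from health.**  Under constant rates the exit time
   from health is exponential with rate $a = \lambda_{hi}+\lambda_{hd}$,
   so the restricted mean PFS time is
   $\mathrm{RMPFST}^{-\tau} = \bigl(1 - e^{-a\tau}\bigr)/a$.  The area
   under the PFS curve up to $\tau_{pfs}$ estimates this restricted
   mean, and the relation is strictly decreasing in $a$, so
   `solve_total_exit_rate()` recovers $a$ by a bracketed Brent solve.

2. **Splitting the exit rate.**  A simultaneous PFS/OS event is a direct
   $h \to d$ transition, so the risk of death for healthy patients
   $\rho = \lambda_{hd}/a$ is estimated by
   $N_\mathrm{simul}/N^e_{pfs}$, giving
   $\lambda_{hd} = \rho\,a$ and $\lambda_{hi} = (1-\rho)\,a$.

3. **Ill-to-dead rate.**  $\lambda_{id}$ is an occurrence/exposure
   estimate: $N_{id}/E_\mathrm{ill}$, with
   $N_{id} = N^e_{os} - N_\mathrm{simul}$ deaths from illness and
   $E_\mathrm{ill} = E_{os} - E_{pfs}$ the person-time spent ill.  When
   censoring times are unreadable from the curve, the person-time of an
   analysis is recovered from summary data alone via an
   inverse-probability-weighting argument: the restricted mean satisfies
   $\mathrm{RMST} \approx \bigl(\tfrac{N^e+N^c}{N^e}\sum o^e_i + \sum
   o^c_j\bigr)/(N^e+N^c)$, and solving this for the unknown censoring-time
   sum and substituting into $E = \sum o^e_i + \sum o^c_j$ gives
   $E \approx \mathrm{AUC}\,(N^e+N^c) + \sum o^e_i\,\bigl(1 -
   \tfrac{N^e+N^c}{N^e}\bigr)$ (`person_time_ipw()`).

`approximate_rates()` composes these steps and reports the person-times,
$N_{id}$ and fitted restricted means as diagnostics.

## Worked example

The packaged fixture holds summary data abstracted from the PFS and OS
analyses of a randomized trial in metastatic epidural spinal cord
compression (MESCC), where the healthy state is the ability to ambulate:

```{r}
run_case_study()
```

## Design choices

Several points are genuinely open when abstracting from published
analyses; the package fixes them as follows.

* **Person-time route.**  `approximate_rates(person_time = "ipw")` (the
  default) uses the summary-only formula above, which is the only option
  for published curves.  When individual records are available,
  summaries built by `summarize_survival_analysis()` carry the censoring
  -time sum and `person_time = "exact"` uses
  $E = \sum o^e_i + \sum o^c_j$ directly.  With no censoring the two
  coincide exactly.
* **KM ties.**  Events are processed before censorings at tied times
  (the standard product-limit convention): a patient censored at $t$ is
  still at risk for an event at $t$.
* **AUC truncation.**  The restricted AUC of each analysis is always
  truncated at that analysis's own maximum observation time $\tau$,
  which is what the restricted-mean inversion requires.  Beyond its last
  step a KM curve is extended as a constant.
* **Simultaneity tolerance.**  `count_simultaneous_events()` matches the
  two event-time multisets one-to-one, greedily after sorting, which is
  maximal for interval matching.  The default tolerance is 0, suited to
  exact simulated or reconstructed times; digitized curves need a
  positive tolerance chosen by the user, since no principled universal
  value exists.
* **Degenerate estimates.**  Heavy censoring can drive
  $E_\mathrm{ill} \le 0$ or $N_{id} = 0$, making the $\lambda_{id}$
  estimate meaningless or even negative.  These are *flagged*
  (`diagnostics$valid`), not errors, and the simulation aggregates
  include them — excluding them would bias the bias study itself, whose
  point is partly that such cells occur.
* **Root finding.**  `uniroot()` (Brent) on $[10^{-12}, a_\mathrm{hi}]$
  with the upper bracket doubled from $1/\mathrm{AUC}$ until it
  straddles the root; absolute tolerance $10^{-12}$.  The solution is
  unique by strict monotonicity.  Tests cross-check it against the
  Lambert-W closed form
  $a = 1/\mathrm{AUC} + W_0\!\bigl(-(\tau/\mathrm{AUC})
  e^{-\tau/\mathrm{AUC}}\bigr)/\tau$.
* **Occupancy closed form.**  Starting healthy,
  $p_h(t) = e^{-at}$ and
  $p_i(t) = \lambda_{hi}\,(e^{-at} - e^{-\lambda_{id}t})/(\lambda_{id}-a)$;
  the removable singularity at $\lambda_{id} = a$ switches to the limit
  $\lambda_{hi}\,t\,e^{-at}$ when the two rates agree to a relative
  $10^{-9}$.  Tests verify the closed form against a matrix exponential
  of the generator.  QALY integrals use the trapezoid rule on the
  caller's grid (default 1000 uniform points); no discounting is
  applied.

## The simulator and the bias study

`simulate_cohort()` draws exact trajectories of the process: healthy
patients draw an exponential exit time at rate $a$, exit directly to
death with probability $\rho$ (PFS and OS events coincide) or progress
and draw an independent exponential ill-state sojourn at $\lambda_{id}$;
baseline-ill patients draw an exponential death time and enter the OS
analysis only.  The default configuration — 100 patients, 75 healthy at
baseline, $\lambda_{hi} = 0.33$, $\lambda_{hd} = 0.53$,
$\lambda_{id} = 3.28$ per year — mirrors the surgical arm of the MESCC
case study, a realistic oncology setting in which illness is rapidly
fatal relative to progression.

Censoring is imposed by `apply_exact_count_censoring()`: exactly $k$
patients per analysis, sampled without replacement, have their
observation replaced by a draw from Uniform(0, event time).  This is the
key reproduction assumption: "uniform censoring achieving given censored
counts" does not pin down the distribution's support, and
Uniform(0, $t_\mathrm{event}$) is the choice that guarantees the exact
counts while keeping every censoring time admissible.  PFS and OS
censoring are independent (cells with more PFS than OS censorings are
otherwise impossible), and the PFS analysis covers only the 75
baseline-healthy patients.  Replications within a cell draw sequentially
from one seeded generator; `run_grid()` derives a deterministic seed per
cell from the base seed, so each cell is reproducible on its own and the
study runs on a single CPU without stream bookkeeping.

`run_replications()` aggregates the mean error (ME), mean absolute error
(MAE) and their percentage versions across replications for the three
quantities the method targets ($a$, $\rho$, $\lambda_{id}$), counting
degenerate replications.  The test suite checks the zero-censoring cell
against its known behaviour at $2\times10^4$ replications and the
censored cells qualitatively (systematic underestimation of $a$) at 400
replications per cell; parameter recovery is checked on one uncensored
cohort of $10^5$ patients within 2%.  These sizes were chosen to keep
Monte-Carlo error comfortably inside the asserted tolerances while the
whole suite runs in well under a minute; `run_simulation_study()`
accepts any replication count for full-scale runs.

## What passing tests do and do not show

The simulator generates data *from the assumed model*, so the bias study
quantifies the approximation error of the summary-data pipeline — the
KM-step AUC, the IPW person-time recovery, the simultaneous-event split
— not model misspecification.  Real data add digitization noise,
time-varying hazards, and tied or interval-recorded times, none of which
the generator emulates.  In particular:

* The censored-cell results depend on the under-specified censoring
  mechanism; a different censoring support changes the numbers (though
  not the qualitative underestimation), so they should be read as
  illustrative, not definitive.
* $\lambda_{id}$ is the fragile quantity: it rests on a difference of
  two approximated person-times and degenerates under heavy censoring.
  The exit rates from health are markedly more robust.
* With tolerance 0, simultaneity counting is exact only when PFS and OS
  event times come from the same records, as in simulation or
  author-supplied data.
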