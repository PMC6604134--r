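# km2rates

Approximate transition rates for illness-death models from published
survival analyses.

## The problem

Many chronic progressive diseases are well described by a three-state
illness-death model — healthy (*h*), ill (*i*), dead (*d*) — with
constant transition rates λ<sub>hi</sub>, λ<sub>hd</sub>, λ<sub>id</sub>
and no recovery.  State-transition (multistate) modelling with these
rates supports extrapolation beyond a study's follow-up and
quality-adjusted life-year (QALY) analysis for cohorts whose baseline
mix differs from the study's — things partitioned-survival modelling
cannot do.  But fitting a multistate model needs individual transition
data, and most published studies report only progression-free survival
(PFS) and overall survival (OS) Kaplan–Meier analyses.

`km2rates` is for health-economic modellers and clinical researchers who
have only those published analyses.  It recovers *approximate* transition
rates from six quantities abstractable per analysis — event count
N<sup>e</sup>, censoring count N<sup>c</sup>, summed event times, the
maximum observation time τ, the restricted area under the KM curve
(AUC), plus the number N<sub>simul</sub> of simultaneous PFS/OS events:

1. Exit from health is exponential at rate a = λ<sub>hi</sub> +
   λ<sub>hd</sub>, so the restricted mean PFS time is
   (1 − e<sup>−aτ</sup>)/a.  Setting this equal to AUC<sub>pfs</sub>
   and solving (the relation is strictly monotone) yields a.
2. Simultaneous PFS/OS events are direct h→d transitions, so the risk of
   death for healthy patients ρ = λ<sub>hd</sub>/a is estimated by
   N<sub>simul</sub>/N<sup>e</sup><sub>pfs</sub>, splitting a into
   λ<sub>hd</sub> = ρa and λ<sub>hi</sub> = (1 − ρ)a.
3. λ<sub>id</sub> = N<sub>id</sub>/E<sub>ill</sub>, with N<sub>id</sub> =
   N<sup>e</sup><sub>os</sub> − N<sub>simul</sub> and E<sub>ill</sub> =
   E<sub>os</sub> − E<sub>pfs</sub>, where each analysis's person-time E
   is recovered from its summary alone by an
   inverse-probability-weighting identity:
   E ≈ AUC·(N<sup>e</sup>+N<sup>c</sup>) +
   Σo<sup>e</sup>·(1 − (N<sup>e</sup>+N<sup>c</sup>)/N<sup>e</sup>).

The package also provides the forward machinery (closed-form
state-occupancy fractions, partitioned-survival curves, QALY integrals),
a cohort simulator for the process, and a Monte-Carlo bias/precision
study of the approximation under exact-count uniform censoring.

## Worked example

The packaged fixture holds summary data abstracted from the PFS and OS
analyses of a randomized trial of decompressive surgery plus
radiotherapy (mS+RT) versus radiotherapy alone (RT-alone) for metastatic
epidural spinal cord compression, with ambulation as the healthy state:

```r
library(km2rates)
run_case_study()
#> Approximate illness-death transition rates
#>
#>       arm     param      rate rate_rounded
#>  rt_alone lambda_hi 0.6474698         0.65
#>  rt_alone lambda_hd 0.9249568         0.92
#>  rt_alone lambda_id 2.1857379         2.19
#>     ms_rt lambda_hi 0.3299004         0.33
#>     ms_rt lambda_hd 0.5223423         0.52
#>     ms_rt lambda_id 3.7165579         3.72
#>
#> Hazard ratios, ms_rt vs rt_alone:
#> lambda_hi lambda_hd lambda_id    rho_rr
#>    0.5095    0.5647    1.7004    1.0419
```

Reading: under radiotherapy alone an ambulatory patient loses ambulation
at 0.65/year and dies directly at 0.92/year (total exit 1.57/year);
non-ambulatory patients die at 2.19/year.  Surgery roughly halves both
exit rates from the ambulatory state (hazard ratios 0.51 and 0.56) while
the estimated mortality of non-ambulatory patients is higher (3.72/year).

How trustworthy are such estimates?  The bias study simulates cohorts at
known rates and pushes them through the same pipeline:

```r
cfg <- cohort_config(seed = 1)   # 100 patients, 75 healthy, rates 0.33/0.53/3.28
run_replications(cfg, 2000)
#>   k_os k_pfs      param        me    mae  pct_me pct_mae n_reps n_degenerate
#> 1    0     0 total_exit -0.001625 0.0791 -0.1890    9.20   2000            0
#> 2    0     0        rho  0.000534 0.0436  0.0867    7.08   2000            0
#> 3    0     0  lambda_id  0.067498 0.3674  2.0579   11.20   2000            0
```

With no censoring the exit rate from health and ρ are essentially
unbiased (mean error ≈ 0) with mean absolute errors around 9% and 7%;
λ<sub>id</sub> carries a small positive bias and ~11% absolute error.
`run_grid(default_censoring_grid(), ...)` extends this over nine
censoring combinations, where the method systematically underestimates
the rates as censoring grows.

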