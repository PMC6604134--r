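Package: km2rates
Title: Approximate Transition Rates for Illness-Death Models from Published Survival Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates approximate transition rates for progressive,
    time-homogeneous three-state (healthy/ill/dead) Markov disease processes
    from summary data abstracted from published progression-free survival
    (PFS) and overall survival (OS) Kaplan-Meier analyses: event and
    censoring counts, summed event times, maximum observation times, and
    restricted areas under the curves.  The total exit rate from health is
    recovered by inverting the exponential restricted-mean survival-time
    relation, split into healthy-to-ill and healthy-to-dead components using
    the count of simultaneous PFS/OS events, and the ill-to-dead rate is
    estimated as events per person-time in the ill state via an
    inverse-probability-weighting approximation of total observation time.
    Also provides closed-form state-occupancy fractions, partitioned-survival
    curves and quality-adjusted life-year integrals for the fitted model, a
    cohort simulator for the illness-death process with exact-count uniform
    censoring, and a Monte-Carlo bias/precision study of the approximation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    Matrix,
    pracma,
    optparse,
    withr
Config/testthat/edition: 3
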