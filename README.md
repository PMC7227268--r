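# nestedcc

Matched nested case-control analysis for longitudinal cohorts with daily
exposure logs.

## The problem

When an exposure of interest was not (and could not be) randomised — such as
formula versus breast-milk feeding in preterm infants at risk of necrotising
enterocolitis (NEC) — a retrospective case-control comparison is misleading:
the outcome changes subsequent exposure, so exposure must be ascertained
*before* each outcome event. The matched nested case-control design solves
this by sampling controls from the cohort members still at risk at the moment
each case occurs (incidence-density sampling), matching them to the case on
key confounders, and evaluating time-dependent exposure strictly before the
event day.

`nestedcc` implements that design end to end for cohorts with an
integer-day time axis (day 0 = delivery/entry) and a long-format daily
exposure log:

- **Risk sets** — at each case's event day `t`, every subject with
  `exit_day >= t`, no event on or before `t`, and no earlier case history is
  eligible; future cases are eligible as controls for earlier cases.
- **Matching** — controls are matched exactly on sex and by minimal
  Mahalanobis distance `sqrt((x_case - x_ctrl)' V^{-1} (x_case - x_ctrl))`
  on gestational age and birth weight, with `V` the sample covariance over
  the whole cohort; boundary ties break uniformly at random; sampling is
  without replacement within a set, with replacement across sets.
- **Exposure classification** — daily logs are truncated strictly before the
  index day, small gaps (≤ 2 days, configurable) flanked by the same feed
  type are filled, and four predefined exposures are evaluated: non-breast
  milk (formula/fortifier) in the first 14 days, first 28 days, any prior
  day, and any feed-type change within the previous 7 days.
- **Estimation** — conditional logistic regression on the matched sets,
  maximising `sum_j [x'_case beta - log sum_k exp(x'_k beta)]` by
  Newton–Raphson with analytic derivatives, Wald 95% CIs, and a separation
  diagnosis; unadjusted and trial-arm-adjusted odds ratios are reported.
- **Simulation** — a cohort generator with known ground truth (correlated
  gestational age / birth weight, arm-dependent exposure hazards calibrated
  to 44% / 23% first-14-day prevalence, discrete-time logistic event hazard,
  feed-log gaps) supports parameter-recovery and design-efficiency
  experiments, including the analytic `m/(m+1)` efficiency ladder for 1:m
  matching.

## Worked example

```r
library(nestedcc)

cfg <- simulation_config(n_subjects = 398, seed = 42)
ch  <- simulate_cohort(cfg)
ch                       #> <ncc_cohort> 398 subjects (26 cases), 21279 feed-log records

sets <- sample_all(ch, matching_spec(controls_per_case = 4), seed = 7)
sets                     #> <ncc_matched_sets> 26 matched sets, 104 control slots

rows <- build_analysis_table(sets, ch, default_exposures(), max_gap = 2)
fits <- fit_exposure_models(rows, names(default_exposures()))
odds_ratio_report(fits)
#> Exposure odds ratios (conditional logistic regression)
#>         exposure adjustment n_cases n_controls odds_ratio            ci converged
#>         first_14 unadjusted      26        104       1.37  (0.51, 3.70)      TRUE
#>         first_14   adjusted      26        104       1.37  (0.50, 3.70)      TRUE
#>         first_28 unadjusted      26        104       1.60  (0.64, 4.02)      TRUE
#>         first_28   adjusted      26        104       1.61  (0.64, 4.06)      TRUE
#>        any_prior unadjusted      26        104       3.11  (1.05, 9.19)      TRUE
#>        any_prior   adjusted      26        104       3.12  (1.05, 9.24)      TRUE
#>  change_within_7 unadjusted      26        104       4.34 (1.37, 13.77)      TRUE
#>  change_within_7   adjusted      26        104       4.34 (1.36, 13.81)      TRUE

baseline_table(ch, sets)   # cases / control slots / non-cases descriptives,
                           # with unique-control and future-case footnotes
```

Each odds ratio compares cases with their matched controls at the case's
event day; "adjusted" adds trial arm as a covariate (sex, gestational age
and birth weight are handled by the matching itself). In this simulated
cohort the true any-prior exposure effect is log 2, and the design recovers
an elevated odds ratio with wide intervals — the expected behaviour at
26 cases.

The same analysis runs from a YAML config and CSV inputs via
`run_pipeline("run.yaml")` or the `exec/ncc` script
(`ncc simulate|sample|analyze|report --config run.yaml`).

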