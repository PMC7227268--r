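---
title: "Methods: matched nested case-control analysis with nestedcc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched nested case-control analysis with nestedcc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestedcc)
```

## The design

A nested case-control study embeds case-control sampling inside a defined
cohort. Each time a subject experiences the outcome (a *case*), controls are
drawn from the *risk set*: the cohort members still under follow-up and
event-free at that moment. Because controls are sampled at the case's event
time (incidence-density sampling), the conditional-logistic odds ratio
estimates the hazard (rate) ratio, and time-dependent exposures can be
evaluated strictly before the event — the property that makes the design
suitable for exposures, such as infant feed type, that are themselves
altered by the outcome.

`nestedcc` works on an integer-day time axis: day 0 is the day of delivery
(cohort entry), and each subject's follow-up ends at `exit_day`, the first
of the outcome event, death, or the last daily log record. A subject whose
event falls on its exit day exits *because of* the event. The package
deliberately records a single exit day without distinguishing death from
loss to follow-up: the risk-set construction only needs to know when
follow-up ends.

### Risk-set rules

At event day `t` of a case, a subject is eligible as a control when

1. `exit_day >= t` — still under follow-up. A subject who exits without an
   event on day `t` itself is still counted as at risk on `t`: this is the
   conservative reading of "still at risk" at a boundary the data cannot
   resolve more finely.
2. it has no event on or before `t`. Consequently two cases sharing an event
   day can never serve as controls for each other; they are processed in a
   seeded random order, since each is excluded from the other's risk set
   either way.
3. it has not previously been a case (a case is a case once; its later
   follow-up never re-enters the pool).

Subjects whose own event comes *later* are eligible — excluding future cases
is a known source of bias in rate-ratio estimation. A subject may be sampled
as a control in any number of sets (with replacement across sets, without
replacement within a set), and the descriptive reporting counts both control
*slots* and unique controls so that this duplication is visible.

### Matching

Controls are matched exactly on sex, and among same-sex eligibles by
smallest Mahalanobis distance on gestational age and birth weight,

$$ d(x, y) = \sqrt{(x - y)^\top V^{-1} (x - y)}, $$

which accounts for the strong collinearity between the two measures: naive
Euclidean matching would effectively match on birth weight alone (its scale
dominates), while the Mahalanobis metric penalises discrepancies along the
direction the cohort does not vary. The metric matrix `V` is the sample
covariance of the two factors over the **whole cohort**, estimated once so
that the metric is identical in every risk set; the population for this
estimate is a genuinely open choice, and a per-risk-set covariance would
make distances incomparable across sets. If the sample covariance is
numerically singular (collinear factors), a small ridge `eps * I`
(default `1e-8`) is added with a warning.

Selection takes the `m` smallest distances (default `m = 4`). Ties *at the
selection boundary* are broken uniformly at random from the seeded RNG;
interior ties are irrelevant to membership. When fewer than `m` same-sex
eligibles exist, all are taken and the set is flagged short rather than
dropped — the fitter handles variable set sizes, and silently dropping short
sets would bias the sample toward well-populated strata. The default of
four controls per case reflects the `m/(m+1)` efficiency ladder (below):
a fifth control buys only ~4% efficiency while increasing repeated sampling
of the scarcest (smallest) infants.

## Exposure classification

The daily feed log records one feed type per subject-day from
`{breast, formula, fortifier, unknown}`. Classification at an index day
(always the matched set's event day, for cases and controls alike) proceeds
in two steps, in a fixed order:

1. **Truncate** the log to days strictly before the index day. The index
   day itself is excluded because a diagnosis changes subsequent feeding;
   nothing on or after the index day may influence any flag, not even by
   supplying the flank of a gap fill. (This ordering is what makes the
   truncation property provable: the suite mutates post-index records at
   random and asserts the flags are unchanged.)
2. **Fill gaps**: an interior run of at most `max_gap` missing days flanked
   on both sides by the *same* recorded feed type is imputed with that
   type; all other missing days — longer runs, conflicting flanks, days
   before the first record — become `unknown`. Recorded values are never
   altered, and `unknown` never counts as exposure nor as a feed change.
   The original study filled "small gaps" without publishing the exact
   rule, so the rule here is the package's own declared stand-in; the
   default `max_gap = 2` days treats a weekend-length hole in an otherwise
   stable regimen as stable, which is the weakest assumption that still
   rescues most routine-data gaps. Setting `max_gap = 0` disables
   imputation entirely.

Three window kinds cover the predefined exposures: `first_k_days` (any
exposed type on days `0 .. min(k, index) - 1`; "first 14 days of life"
means days 0–13, half-open `[0, 14)`), `any_prior` (any exposed day before
the index), and `change_within_k` (two consecutive days of *known* feed
type differing, within the `k` days before the index; `unknown` breaks the
chain, because a change "between formula, fortifier or breast milk" is a
statement about known types). Fortifier counts as exposure alongside
formula throughout. These definitions are nested by construction
(`first_14 => first_28 => any_prior`) and monotone in the index day —
both properties are asserted over random logs in the test suite.

## Conditional logistic regression

With exactly one case per set (guaranteed by construction), the
conditional likelihood for coefficient vector $\beta$ is

$$ \ell(\beta) = \sum_j \left[ x_{j,\mathrm{case}}^\top \beta -
   \log \sum_{k \in j} \exp(x_{j,k}^\top \beta) \right], $$

the Breslow form, with no tie-handling variants needed. Sets whose members
share identical covariate vectors contribute the constant $-\log(\text{set
size})$; they are retained and counted as non-informative rather than
silently dropped. Fitting is Newton–Raphson from $\beta = 0$ with analytic
gradient and Hessian, step-halving on any step that decreases
$\ell$, and convergence when the gradient max-norm falls below `1e-8` or
the relative change in $\ell$ below `1e-10`. The likelihood is concave, so
the only failure mode is separation — an exposure that perfectly predicts
case status makes the supremum unattainable. The fitter flags a fit as
separated (and not converged) when a coefficient passes ±10 on the log-odds
scale (an odds ratio beyond ~22,000 is a diagnosis, not an estimate) and
reports the direction of divergence. Confidence intervals are Wald,
$\exp(\hat\beta \pm 1.96\,\mathrm{se})$, from the inverse observed
information; the original report does not state its CI method and Wald is
the standard choice for this model. For 1:1 sets with a binary exposure
the MLE reduces to the discordant-pair closed form $n_{10}/n_{01}$, which
the suite checks to `1e-8`, alongside an independent optimizer
(`survival::clogit`) on 1:4 data.

Adjustment for trial arm enters as an ordinary covariate ("adjusted"
fits); sex, gestational age and birth weight are controlled by the matching
itself. Trial arm is deliberately *not* a matching factor: it strongly
predicts the exposure (it sets the feeding regime) but showed no
association with the outcome, so matching on it would be overmatching.

## The simulator

`simulate_cohort()` emulates the study population at configurable scale so
that every stage has a testable ground truth:

- **Baseline**: sex (`p_male = 0.53`); gestational age
  `N(30, 2.5^2)` weeks floored at 23; birth weight
  `-1800 + 90*GA + N(0, 230^2)` g floored at 250. The slope and residual SD
  imply a GA–BW correlation of ~0.70 (checked within ±0.05 at n = 20,000),
  and the medians land near a growth-restricted preterm population (~900 g
  at 30 weeks). These are illustrative values loosely matched to published
  descriptives of such cohorts, not estimates from any dataset.
- **Feeding**: each subject starts on breast milk; each day on breast milk
  it switches to a non-breast episode (formula or fortifier, 50/50) with an
  arm-specific hazard, and each non-breast day reverts with probability
  0.03 (small, so exposure is near-monotone but feed-type *changes* occur).
  Under a constant hazard the first-14-day exposure probability is
  `1 - (1-h)^14`, so the hazards hitting the 44% (early arm) and 23% (late
  arm) targets are computed exactly as `h = 1 - (1-p)^(1/14)` — a closed
  form rather than a numeric calibration, fixed once in code.
- **Events**: a discrete-time logistic hazard on days 1..56 with linear
  predictor `logit(h0) + bE * any_prior_exposure + bGA * (GA - 30) +
  bBW * (BW - 900)/100`; defaults `bE = log 2`, `bGA = -0.25/week`,
  `bBW = -0.1/100 g`, and `h0 = 0.00085` calibrated once so the default
  configuration yields ~9% cumulative incidence. A discrete-time logistic
  (not continuous-time exponential) hazard matches the integer-day time
  axis, and under rare events its exposure log-odds coefficient is the
  estimand of the conditional-logit analysis, which is what makes the
  recovery experiment interpretable.
- **Gaps**: each feed-log day is deleted independently with `gap_rate`
  (default 3%).

What the generator does *not* emulate: the clinical randomisation protocol
beyond its effect on exposure hazards, mortality as distinct from
censoring, seasonal or centre effects, and informative missingness in the
logs (gaps are completely at random). Passing recovery tests therefore
demonstrate internal consistency of design + estimator under a correctly
specified hazard, not robustness to those real-data features.

`constrain_case_count()` administratively censors a simulated cohort at its
n-th event day, yielding an exact case count (tied later events are demoted
to censoring at the cutoff); it exists for design checks such as "35 cases
× 4 controls = 140 selections" and is labelled a synthetic device, not part
of the analysis path.

## Efficiency of 1:m matching

With matched sets and a common effect, the Pitman efficiency of 1:m
matching relative to the full-cohort limit is `m/(m+1)`: 1:1 achieves 50%,
1:4 achieves 80%, 1:5 achieves 83.3%, so the step from four to five
controls gains `((5/6)/(4/5) - 1) * 100 ≈ 4.17%` — the analytic version of
"little is gained beyond four controls". `efficiency_table()` tabulates the
ladder; `recovery_experiment()` verifies it empirically, running m = 1 and
m = 4 on the *same* simulated cohorts so the variance ratio
(expected `(1/0.5)/(1/0.8) = 1.6`) is a paired contrast.

## Problem sizes and numerical choices

The package's simulation checks run at sizes chosen to separate signal from
Monte-Carlo noise while staying desk-scale: calibration checks (exposure
prevalence, GA–BW correlation, closed-form event counts) use single cohorts
of n = 20,000 with 3-SD binomial tolerances; the recovery experiment uses
n = 2,000 subjects × 200 replicates with m ∈ {1, 4} (about 180 cases per
replicate), which puts the Monte-Carlo SE of the mean log-OR near 0.012 —
comfortably inside the ±0.1 recovery band — and the matching-versus-brute-
force oracle sweeps 100 random cohorts of n = 50. Tolerances on exact
quantities (closed forms, gradients) are `1e-6`–`1e-8`; tolerances on
stochastic quantities are pre-stated binomial/relative bands, not tuned.

Degenerate inputs are handled explicitly rather than silently: empty risk
sets warn and propagate as empty flagged sets; zero-variance matching
factors are an error naming the factor; collinear factors trigger the
ridge; concordant-only data refuse to fit ("no discordant sets");
separation is flagged with direction; sets that lost all controls are
dropped by the fitter with a warning.

## Limitations

- Matching controls only measured confounders; the design cannot balance
  unmeasured ones, and the simulator's recovery results assume the hazard
  model is correctly specified.
- The gap-filling rule is a declared assumption; sensitivity to `max_gap`
  should be reported for real analyses.
- Greedy per-set matching in event order is the study's algorithm; no
  globally optimal assignment across sets is attempted, and no
  counter-matching or caliper variants are provided.
- Wald intervals can undercover in very sparse sets; profile-likelihood
  intervals are not implemented.
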