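---
title: "Modelling multi-stage training progression in discrete time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multi-stage training progression in discrete time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtprog)
```

## The process being modelled

UK psychiatry training is an ordered sequence of six annual levels,
CT1–CT3 (core) then ST4–ST6 (specialty). Progression is observed once a
year in registry data: one row per person per year carrying the current
training level and person-level covariates. The quantity of interest is
the probability of traversing all five transitions in consecutive
years — completing training in the minimum six years — and how that
probability differs across demographic and socioeconomic groups.

Time here is genuinely discrete: an event (failing to progress) can
only be observed at one of five annual transition points. A
continuous-time proportional-hazards model would face massive ties and
an artificial time scale; the natural formulation is a discrete-time
hazard model on a person–period dataset.

### Event definition

The event at transition $t$ is *failure to appear at the expected next
level in the next calendar year* — whether the person is absent from
the records, still at the same level, or at a lower level. Drop-out,
exam failure, career breaks, switching specialty, and less-than-full-time
progression are deliberately conflated: annual level snapshots cannot
distinguish them, and the completion-in-minimum-time question does not
require distinguishing them. The complement — "survival" — is on-time
progression.

## The hazard model

For person $i$ at risk in period $t \in \{1,\dots,5\}$ with covariate
vector $x_i$,

$$\operatorname{logit}\, h_t(x_i) = \beta_t + \textstyle\sum_k \beta_k x_{ik},$$

a Bernoulli likelihood over all person–period rows. The five time
dummies are *entered as intercepts*: there is no global intercept, so
each $\beta_t$ is directly the log-odds of non-progression at
transition $t$ for the reference covariate pattern. A design with a
global intercept plus four dummies would be an equivalent but silently
different parameterisation, so the model matrix is built internally and
only the no-intercept form exists. Cumulative survival is
$S_t = \prod_{j \le t}(1 - h_j)$.

Because every covariate is time-constant, $\exp(\beta_k)$ is the
per-period odds ratio at *every* transition — the proportional-odds
assumption holds by construction rather than by diagnostic. Survival
curves for two patterns differing in one covariate therefore never
cross.

Event coding follows the case definition: event = 1 is non-progression,
so an odds ratio above 1 for a group means higher per-period odds of
not progressing, i.e. lower odds of completing on time. Recoding the
reference category of a covariate (the `reference` argument of
`fit_hazard_model()`) flips the coefficient's sign and inverts the odds
ratio exactly.

### Estimation and numerical choices

* **Optimizer.** Damped Newton (iteratively reweighted least squares
  with step halving). Convergence when the largest score component is
  below $10^{-8}$ or the relative change in $-2\ell$ is below
  $10^{-10}$; iteration cap 100. At convergence detection one full
  Newton *polish* step is taken (accepted only if $-2\ell$ does not
  increase): quadratic convergence squares the residual, so the
  intercepts-only fitted hazards agree with the empirical event
  proportions $d_t/n_t$ to machine precision, which in turn makes the
  Kaplan–Meier/discrete-baseline identity below exact in floating
  point.
* **Covariance.** Inverse observed information at the optimum
  (identical to expected information under the canonical logit link);
  Wald 95% intervals use the 0.975 normal quantile.
* **Degenerate designs.** The design matrix is rank-checked before
  fitting; a constant covariate (collinear with the time dummies) or a
  duplicated covariate raises an error naming the offending column.
  Coefficients exceeding 12 in absolute value after convergence trigger
  a complete-separation warning — the fit is returned, flagged, never
  silently.
* **Missing data.** Complete-case *per model*: rows of persons missing
  any requested covariate are dropped and the count reported. Because
  the row set then depends on the covariate list, the likelihood-ratio
  test refuses models fitted on different rows; `drop_missing_on`
  lets a reduced model be fitted on exactly the rows of a fuller one.
* **Pseudo-$R^2$.** Both Cox–Snell,
  $1 - \exp\{(-2\ell_{\text{full}} + 2\ell_0)/n\}$ against the
  time-dummies-only model on the same rows, and its Nagelkerke
  rescaling are reported, because published values are often unlabelled
  and common software prints both.
* **Interactions.** An interaction term enters the final model when its
  Wald test is significant at $\alpha = 0.05$ *or* $-2\ell$ improves by
  at least 4 — inclusive at the boundary, so an improvement of exactly
  4 includes the term. Wald rather than likelihood-ratio significance
  is the default for the first clause (the LR statistic remains
  available through `lr_test()`).

## Cohort construction rules

`select_entry_cohort()` keeps each person's *first* appearance at the
entry level inside the entry window. "Stayers" — non-progressors who
reappear at the same level in later years — therefore enter once, at
their first attempt; their duplicate rows are not discarded, though:
they confirm non-progression in the event walk. Persons first seen at
the entry level before the window are excluded outright (a later
duplicate row must not re-admit them). Persons whose first observed
entry-level year is the first data year are kept even though their
prior history is unobservable; this left-censoring means completion
probabilities are, if anything, slightly overestimated.

`build_person_period()` emits, per person, event-free rows while the
expected level appears on schedule, one final event row when it does
not, and nothing at all for periods beyond the horizon year
(administrative right censoring). Censoring is thus handled by risk-set
membership, not by a censoring indicator: a person censored after
period $t$ appears in risk sets $1..t$ and nowhere later. A cohort with
entry window 2012–2013 and horizon 2018 has no right censoring at all,
which is what makes it a useful sensitivity subcohort.

The calendar convention is that a record year labels the academic year
ending in it, and every transition resolves exactly one calendar year
after the previous level was held. Records violating the trajectory
invariants (level regression, or a climb faster than one level per
elapsed year) are rejected as corrupt rather than interpreted — once
validation passes, a CT1 entrant can never legitimately be observed
*above* the expected level, so no guessing rule is needed.

## Sensitivity estimators

`km_estimate()` is the product-limit estimator with event time equal to
the event period and censoring time equal to the last at-risk period.
Because censoring happens at period boundaries *after* the risk set is
counted, the KM risk set at time $t$ is exactly the person–period rows
at $t$, hence $\hat h_t = d_t/n_t$ and the KM curve is identical to the
intercepts-only discrete-time baseline — an algebraic identity the test
suite asserts to $10^{-10}$, not an approximation.

`life_table()` is the actuarial estimator with the standard
half-withdrawal convention (effective at-risk $n_t - c_t/2$). It
differs from KM only through that convention, converges to KM as
censoring vanishes, and its deviation is reported, not constrained, by
`compare_estimators()`.

## The synthetic registry scenario

Real registry data of this kind are access-restricted, so the package
is exercised end-to-end on `training_scenario()`, a documented preset
of the generator. What it emulates, and the default values:

* **Entry cohorts 2012–2017**, near-uniform weights; administrative
  censoring at 2018.
* **Reference-pattern hazards** $(0.097, 0.106, 0.417, 0.130, 0.131)$.
  These were calibrated once, by fixed-point simulation at large $n$,
  so that the *cohort-level* hazards — after the covariate effects act
  on a realistic covariate mix — come out near
  $(0.20, 0.21, 0.571, 0.21, 0.21)$: about a fifth of entrants fail
  the first transition, the core-to-specialty competition is a
  pronounced bottleneck near 57%, and roughly 17% of the cohort
  completes in six years. The split of the non-bottleneck hazards is
  the equal-share solution consistent with that completion
  probability.
* **Covariate effects on the hazard logit** (non-reference category,
  event scale): gender +0.40, non-UK qualification +0.77, minority
  ethnicity +0.26, disability +1.02, childhood free school meals
  +0.66, most-deprived-area residence +0.39, with school type,
  graduate entry and parental degree near zero. Magnitudes mirror the
  per-period odds ratios reported for UK training-progression cohorts
  of this kind; prevalences (59.6% female, 32.4% non-UK, etc.) match
  the published cohort composition.
* **Stayers**: a non-progressor reappears at the same level with
  probability 0.1, for one or two extra years (never more) — enough to
  exercise first-attempt de-duplication without dominating the record
  stream. Trainees who neither progress nor stay simply vanish; the
  generator does not label why, mirroring the event definition.
* **Missingness**: person-level, completely at random, on the
  socioeconomic covariates at rates whose union removes roughly a
  quarter of the cohort from complete-case multivariable models — the
  case-loss regime such registry analyses report.
* **Randomness**: one master seed spawns independent substreams for
  entry years, covariates, transitions, stayers and missingness, so
  adding a covariate to a configuration does not perturb the
  transition draws — trajectories are comparable across nested
  configurations at the same seed.

What the generator does *not* emulate: correlated covariates (free
school meals and area deprivation are independent here, though an
association knob can be built from `covariate_specs`; no default
correlation is asserted because none is published), informative
missingness, time-varying covariates, extended (>3-year) specialty
programmes, and pre-window training history. Tests passing on this
scenario therefore demonstrate correctness of the *machinery* —
selection, person-period construction, likelihood, estimators,
disclosure — under the model's own assumptions, not robustness to the
ways real registry data violate them.

## Disclosure control

Published outputs pass through the rounding and suppression rules used
for higher-education statistics: counts of 0–2 become 0, all other
counts round to the nearest multiple of 5 (integer counts never tie),
percentages on unrounded bases below 22.5 are suppressed, and averages
over seven or fewer values are suppressed. Two deliberate readings:
suppression thresholds apply to the *unrounded* base (a threshold of
22.5 is only meaningful pre-rounding), and every internal computation
uses raw values — disclosure is a property of the reporting boundary,
applied by `disclose_table()` and friends, never of the analysis.
Non-integer counts are rejected rather than rounded, which keeps the
half-way tie question moot.

## Problem sizes used in the test suite

The suite checks the oracle identities (empirical hazards, KM
equivalence) on cohorts of 1,500–5,000 trainees; parameter recovery on
a single 20,000-trainee scenario cohort (every generating log-odds
within three standard errors); and calibration on 500 replicated
cohorts of 5,000 (95% Wald interval coverage of non-null effects within
[0.90, 0.98], and type-I error of the likelihood-ratio test on a null
covariate within [0.03, 0.07] at $\alpha = 0.05$). These sizes give
Monte-Carlo error comfortably inside the asserted bands while keeping
the whole suite to a couple of minutes.

## Known limitations

* Completion beyond six years is invisible: a trainee who progresses
  slowly and a trainee who leaves are the same event.
* Left censoring at the first data year is acknowledged, not modelled.
* Covariates are dichotomies by design (matching the registry's
  published recodes); multi-level factors are rejected rather than
  expanded.
* Wald intervals can misbehave near separation; the model warns rather
  than switching to profile likelihood.
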