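---
title: "Modelling impulsive intertemporal choice with a multi-attribute DDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling impulsive intertemporal choice with a multi-attribute DDM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itcddm)
```

## The scientific question

Smartphone separation is a context manipulation: take the phone away,
and people report more state anxiety and choose smaller-sooner rewards
more often. `itcddm` implements the computational chain that turns that
observation into a mechanistic account: a drift diffusion model (DDM)
whose drift rate is built from the attributes of each option pair, so
that "more impulsive" can be located in a specific quantity — the
decision weight on the money difference — and then carried into a
mediation analysis (separation raises state anxiety, anxiety lowers the
money weight, a lower money weight produces immediate choices).

## The model and its assumptions

Evidence `R` for the larger-later (LL) option accumulates as a
Brownian motion with drift `v` and diffusion coefficient `s` between
two absorbing boundaries at `0` and `a`, starting at `z * a`. Choice is
the boundary reached; RT is the crossing time plus the non-decision
time `t0`. The drift is linear in the attribute differences:

`v = dc + Wm * MoneyDiff + Wd * DelayDiff`

with `MoneyDiff` in raw money units and `DelayDiff` in days — no
normalisation, so `Wm` is evidence per second per money unit and `Wd`
evidence per second per day. A patient decision maker has a large
positive `Wm` relative to `|Wd|`; shrinking `Wm` tilts choices toward
the immediate option. The model assumes:

* stationarity within a trial (no collapsing bounds, no attention
  switching between attributes);
* no across-trial parameter variability (`sv`, `sz`, `st0` are not in
  the model);
* upper boundary = delayed/LL option, lower = immediate/SS option.

**Noise scale.** `s`, `a` and the drift parameters are jointly
non-identifiable (rescaling `s -> c s`, `a -> c a`, `v -> c v` leaves
the data distribution unchanged; the package asserts this numerically
in its tests). We therefore fix `s = 1` and never fit it. Conventions
that fix `s = 0.1` are a deterministic rescaling of all reported
parameters by 0.1.

## Likelihood and numerics

The likelihood of a trial is the Wiener first-passage-time density at
its observed boundary, evaluated at `rt - t0` with the trial's drift.
Two series expansions of the dimensionless kernel are implemented
(small-time and large-time); each evaluation picks whichever needs
fewer terms at truncation tolerance `1e-10`. The two branches agree to
better than `1e-8` in their overlap region and the two boundary
densities integrate to 1 within `1e-4` across the tested parameter
grid — both are asserted in the test suite rather than assumed.

Numerical choices, all surfaced as arguments:

* **Density floor.** A trial whose RT does not exceed the candidate
  `t0` contributes a floored density of `1e-12`, keeping the objective
  finite instead of `-Inf`; the optimiser then moves `t0` down.
* **Simulation.** Euler–Maruyama with `dt = 0.001` s and a
  Brownian-bridge crossing correction inside each step: after stepping
  from `x` to `x'`, the bridge crosses the upper boundary with
  probability `exp(-2 (a - x)(a - x') / (s^2 dt))`, and similarly below.
  This removes the `O(sqrt(dt))` boundary bias of the naive scheme, so
  simulated choice fractions can be compared to the closed-form
  absorption probability at Monte-Carlo precision. Decision times are
  censored at 20 s and flagged.
* **Optimisation.** Bounded L-BFGS-B on the negative log-likelihood;
  bounds `a` in (0.1, 5), `z` in (0.05, 0.95), `t0` in (0, min(rt) - 1 ms),
  weights in (-1, 1), `dc` in (-5, 5). Starts are 8 Latin-hypercube
  draws plus a centre start; all starts are screened by objective
  value, the best four get a short exploration run, and the best two of
  those are polished. This keeps one participant's fit around a third
  of a second without losing the multistart protection against local
  minima.
* **Starting-point mode.** Whether `z` is estimated freely or pinned at
  0.5 is not something the underlying reports settle; both are
  supported (`fixed = list(z = 0.5)`), free estimation is the default.
* **Bayesian mode.** A non-hierarchical random-walk Metropolis sampler
  with reflection at the bounds and weak priors (`z ~ Beta(2,2)`,
  `a ~ half-normal(2)`, `t0 ~ U(0, min rt)`, `dc ~ N(0, 10)`, weights
  `~ N(0, 10 / mean |attribute difference|)`); the point estimate is the
  posterior mean, and posterior-predictive summaries draw one sample
  per replicate. A full hierarchical model with group-level nodes is
  deliberately out of scope: the quantities this package reports —
  individual weights and their group contrasts — are recoverable
  without partial pooling, and the per-participant likelihood is the
  same object a hierarchical wrapper would use.

Posterior-predictive summaries follow the reporting convention of the
emulated analyses: 500 simulated datasets per participant over the
fitted pair menu, summarised as the probability of choosing the
delayed reward and the mean RTs of delayed and immediate choices.

## Task scoring conventions

* **Titration.** The indifference point is the midpoint between the
  largest immediate amount at which the delayed option was still chosen
  and the smallest accepted one. All-delayed series are censored high
  (grid max + half step = 205 on the default grid), all-immediate
  series censored low (grid min − half step = 5, floored at 0).
  Non-monotone series are scored at the first switch and flagged
  (`multi_switch`) rather than dropped — deterministic and auditable.
* **Discounting.** The hyperbolic form `V = A / (1 + kD)` is the
  standard delay-discounting model and the package default; the
  exponential form sits behind `form = "exponential"`. "Two months" is
  taken as 60 days, so `k` is per day.
* **Purchase scenarios.** Restaurant waiting time (5–60 min) is
  reverse-coded as `65 - wait` before z-scoring; the movie timing scale
  (1 = before the deadline) as `101 - timing`; gift compensation is
  kept as-is. Standardisation uses the sample SD (n − 1), matching
  common statistical-package behaviour; a population-SD variant is
  available.

## Inferential layer

Two-group one-way F tests are computed from group summaries (pooled
variance, `F = t^2`), so printed means/SDs/ns of a report can be
re-analysed; `eta_sq = F df1 / (F df1 + df2)`. Covariate adjustment
uses a Type III test on the additive linear model (identical to Type II
here); education and job enter as unordered dummy-coded factors, age
and income as numbers — a conventional choice, since no source settles
it. Mediation is ordinary least squares path analysis with case-resampled
percentile bootstrap intervals (5,000 resamples by default, the PROCESS
convention; not BCa), variables z-scored once before resampling, and the
binary treatment coded 0 = control, 1 = separated. The serial
two-mediator model reports all three indirect paths; the
parallel multiple-mediator model enters mediators jointly in the
outcome equation. All p-values are two-sided.

The printed-statistics table (`printed_statistics()`) flags which
reported rows are actually recomputable: ANCOVA rows whose implied
denominator degrees of freedom are inconsistent with the design, and
rows whose inputs are printed to one or two significant figures (the
attribute-weight Fs), are carried for reference but excluded from the
reproduction bound; the recoverable rows reproduce to within 1% (F)
and 3 decimals (eta squared).

## What the synthetic cohorts emulate — and what they do not

The generator draws study-shaped data with known ground truth:

* **Separation cohort** (36 per group, 80-pair menu crossing four
  immediate amounts, four delayed amounts and five delays around the
  "17 now vs 38 in 30 days" anchor; 80 trials per participant by
  default). Latent DDM parameters come from group distributions with
  the money weight at 0.047 ± 0.029 (control) vs 0.023 ± 0.026
  (separated) and a delay weight of about −0.009 ± 0.002 in both; `a`,
  `t0`, `z`, `dc` share common distributions (1.6 ± 0.3, 0.35 ± 0.08,
  0.5 ± 0.05, 0 ± 0.1) chosen to give realistic RTs around a second.
  State anxiety is 37.50 ± 7.25 vs 29.11 ± 4.23 with no trait shift;
  the SAS total correlates with state anxiety at 0.414 in the
  separation group only. Within groups, the money weight is coupled to
  state anxiety at a standardised −0.5 — an anxiety–weight association
  of the size such experiments report — which is what makes the serial
  mediation chain (group → anxiety → weight → immediate choices)
  emerge mechanically from the DDM rather than being painted onto the
  outcome variable.
* **SAS items.** Totals are built from 11 parallel items:
  `sigma_T^2 = alpha S^2 / k^2` per-item true-score variance and
  `sigma_e^2 = (1 - alpha) S^2 / k` item noise reproduce a target total
  SD `S` and reliability `alpha` (default 0.80) exactly at the latent
  level; the latent correlation with anxiety is `r / sqrt(alpha)`.
  Items are continuous within [1, 5] (truncation by resampling, not
  clipping): with a total SD near 2.8 on an 11–55 scale, integer Likert
  coarsening would dominate the item variance and destroy the targeted
  reliability, and no targeted constraint lives at the item level.
* **Titration cohort.** Latent `k` is lognormal (median ≈ 0.0082 per
  day, matching indifference points around 134 on the 10–200 grid);
  choices are logistic in the gap between the offer and the hyperbolic
  present value (temperature 8 money units). SAS totals are independent
  of `k`, emulating the null association the survey studies report.
* **Survey cohort** (n = 113). A standardised addiction score loads on
  three candidate mediators (extended self 0.45, FoMO 0.40, social
  threat 0.30); anxiety is driven by the extended self (0.40) plus a
  small direct path (0.12), so the extended self is the true mediator
  while the other two are correlated decoys.
* **Mediation truth generator.** Unit-variance structural equations
  with configurable paths; the true serial indirect effect is exactly
  the configured product (default 0.6 × 0.5 × 0.4 = 0.12).

What passing tests on these cohorts shows: the estimation and
inference machinery recovers known structure at the studies' sample
sizes, with calibrated intervals and correctly null nulls. What it does
not show: anything about real response styles, item content, missing
data, menu composition effects, or the unreleased raw data — the
generated menus and trial counts (80 pairs, 80–200 trials) are
documented configuration, not facts about the original task.

## Calibration checks and their interpretation

The study-scale calibration checks cover: simulator choice
fractions within 3 binomial SEs of the closed form at n = 100,000 per
grid point; money-weight recovery on 36-per-group cohorts of 200-trial
participants (rank correlation ≥ 0.8, group contrast significant in
≥ 80% of replicates — the power arithmetic needs the full two-group
design, which is why the replicates are 72-participant cohorts); serial
indirect recovery within ±0.04 of 0.12 at n = 72; and interval
calibration over alternative and null-indirect datasets. For the
"null" calibration the final path `b2` is set to zero while the
upstream paths stay active: with every path null the product statistic
is famously conservative (rejection far below the nominal level), so
the informative 5%-level check is the null-indirect configuration in
which the bootstrap test is approximately exact. Problem sizes in the
routine test suite are scaled to what a laptop runs in minutes; the
acceptance script reruns the same checks from scratch at documented
sizes.

## Known limitations

* No hierarchical pooling; participants with few or one-sided trials
  get flagged, not shrunk.
* The Metropolis sampler is serviceable for the six-parameter
  likelihood but makes no convergence diagnostics beyond seeded
  reproducibility; treat the Bayes mode as a cross-check on the MLE,
  not as a production posterior.
* The ANCOVA path is exercised with noise demographics — the emulated
  reports give no covariate distributions, so covariate-adjusted Fs are
  mechanically correct but not numerically comparable to the originals.
* Censored titration series enter `k` through their censored
  indifference codes; analyses sensitive to the tails should filter on
  the `censored` flag.
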