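# itcddm

Multi-attribute drift diffusion modelling of impulsive intertemporal
choice, with the surrounding behavioural and inferential toolchain:
delay-discounting task scoring, group contrasts with effect sizes,
scale reliability, percentile-bootstrap mediation, and a fully seeded
synthetic-cohort generator that emulates smartphone-separation
experiments end to end.

## Who this is for

Researchers in decision neuroscience and behavioural science who study
how context (here: being separated from one's smartphone) shifts
intertemporal preferences, and who want the full computational chain —
from trial-level evidence-accumulation modelling to the mediation
analysis that links anxiety, attribute weights and impulsive choice —
as tested, reproducible code rather than a pile of toolbox calls.

## The model

A binary intertemporal choice ("17 today, or 38 in 30 days?") is
modelled as a two-boundary diffusion: relative evidence `R` accumulates
in small time steps, `R(t+dt) = R(t) + v dt + s sqrt(dt) N(0,1)`, until
it is absorbed at the upper boundary (choose the larger-later reward,
LL) or the lower boundary (choose the smaller-sooner reward, SS).
Choice is the boundary reached; reaction time is the crossing time plus
a non-decision time `t0`. The drift rate is a linear function of the
two attribute differences of the option pair,

```
v = dc + Wm * MoneyDiff + Wd * DelayDiff
```

where `MoneyDiff = amount_LL - amount_SS` (money units) and
`DelayDiff = delay_LL - delay_SS` (days). Six parameters are estimated
per participant: relative starting point `z`, boundary separation `a`,
non-decision time `t0`, drift constant `dc`, and the attribute weights
`Wm` and `Wd`; the diffusion noise `s` is fixed at 1 for
identifiability. The likelihood is the Wiener first-passage-time
density, evaluated by dual small-time/large-time series expansions; the
simulator is Euler–Maruyama with a Brownian-bridge crossing correction
so that simulated choice fractions converge to the analytic absorption
probability at `O(dt)`.

Around the model sit the classical instruments: titration indifference
points with hyperbolic discounting `k = (A/V - 1)/D`, impulsive-choice
counts, scenario-based impulsive-purchase scores, one-way
ANOVA/ANCOVA with eta squared, Pearson correlations, Cronbach's alpha,
median splits, and simple/parallel/serial mediation with percentile
bootstrap confidence intervals (5,000 case resamples by default).

## Worked example

```r
library(itcddm)

# a participant who weighs money like the control group
truth <- ddm_params(z = 0.5, a = 1.5, t0 = 0.3, dc = 0, wm = 0.047, wd = -0.009)
pair  <- choice_pairs(17, 0, 38, 30)
drift_rate(truth, pair)
#> [1] 0.717
choice_probability(drift_rate(truth, pair), a = 1.5, z = 0.5)
#> [1] 0.7456415

# simulate a session over the 80-pair menu and fit the model back
set.seed(1)
menu   <- generate_choice_menu()
trials <- simulate_trials(truth, menu[rep(1:80, length.out = 200), ])
fit    <- fit_ddm_individual(trials, seed = 1)
fit
#> DDM fit (mle, 200 trials, converged)
#> Multi-attribute DDM parameters (noise s = 1 )
#>       z       a      t0      dc      wm      wd
#>  0.4451  1.5386  0.2963  0.4137  0.0401 -0.0099
#> NLL: 147.678
```

The fitted weights recover the generating values to within sampling
error at 200 trials: the money weight (here 0.040 vs a true 0.047) is
the quantity whose group difference carries the separation effect. A
whole experiment, scored and analysed:

```r
report <- run_study(3, seed = 1, n_boot = 1000)
report$tables$group_contrasts[, c("outcome", "m1", "m2", "f", "p", "eta_sq")]
# state anxiety higher under separation, money weight lower,
# more immediate choices - with F and eta^2 per contrast
report$tables$mediation
# serial indirect effect of separation on impulsive choice
# through state anxiety and the money weight
```

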