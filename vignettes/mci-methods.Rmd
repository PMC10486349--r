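---
title: "Models and methods behind mcisim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mcisim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcisim)
```

mcisim models a cage-mounted touchscreen enrichment device for rhesus
macaques: a home screen with three buttons from which the animal freely
selects, trial by trial, a *static reach* task (touch a stationary disc),
a *dynamic reach* task (touch a bouncing disc), or a *picture viewing*
task (a 5 s image, intrinsically rewarding but never fluid-rewarded).
The package contains the task engine, a generative behavioral agent with
known ground-truth parameters, and the three analysis stages such data
support: engagement, task preference, and task proficiency. This
vignette explains the models, the defaults, and the numerical choices.

## The task engine

All engine coordinates are degrees of visual angle, origin at the
bottom-left screen corner, x rightward, y upward. The default geometry
is a 30.4 cm by 22.8 cm panel viewed from 24 cm; overall extents map to
degrees symmetrically about the screen center
(`2 atan(extent / 2 / distance)`), and individual stimulus sizes use the
linear tangent scale `cm = distance * tan(deg)`. The *task bar* is the
bottom strip of the screen (default 7 degrees: the 5-degree buttons plus
a margin; the height is a configuration field because the physical
device does not document it). The *background region* -- screen minus
task bar -- is where targets live, and a touch there scores: on the disc
(boundary inclusive, a measure-zero convention fixed for determinism) it
is a **hit**, elsewhere in the background a **failure**. Touches on the
task bar during a trial, including on the still-visible selected button,
carry no outcome. No touch within the 5 s timeout makes the trial
**ignored**. Hits trigger an acoustic "ding" and exactly 0.37 mL of
fluid; every outcome is followed by an inter-trial interval drawn
uniformly from 1.5--2.5 s.

Targets spawn with their disc fully inside the background region
(uniform over admissible centers) -- spawning partially off-region discs
would make some trials geometrically unwinnable. Dynamic targets move
with constant speed (drawn per trial from the integer grid 10..30 deg/s;
sizes from 5..10 deg -- integer grids because 21 distinct speed values
is what a per-trial randomization over that range produces) and reflect
specularly off the region boundary. `step_target()` computes reflections
analytically by unfolding the trajectory into a triangle wave, so a step
of any length is exact: speed is conserved to machine precision and the
disc cannot tunnel out of the region at any `dt`.

Button layouts are uniform random bijections of the three tasks onto
the left/middle/right positions, re-drawn every 60 minutes within a
session. Whether the device's "pseudorandomization" allowed immediate
repeats is not documented; the engine defaults to rejecting a repeat of
the previous arrangement (`allow_repeat = FALSE` exposes the choice).

The *chance level* of a target size is the probability that an
uninformed touch lands on the disc: the stimulus-to-background surface
ratio, which scales exactly as the squared diameter. The chance levels
in common use with the reference apparatus (7.33% to 30.24% across
sizes 5 to 10) are *not* reproducible from a pure area ratio at the
documented geometry -- their size scaling deviates from quadratic by a
few percent, suggesting pixel-level rounding or a rendered background
that differs from the idealized rectangle. The package therefore
computes the area ratio from configured geometry by default and accepts
an explicit per-size calibration table (`xbi_chance_table()`) wherever a
chance source is consumed; analyses of device data should pass the
table, synthetic-data studies may use either consistently.

## The synthetic agent

Each agent is a parameter vector with three behavioral subsystems,
deliberately built as the generative mirror of the analysis stages so
that every stage has a recoverable target.

**Engagement.** Trial initiations follow a nonhomogeneous Poisson
process with intensity `lambda(t) = lambda0 * exp(-k t / T)` over the
session `[0, T]`, sampled by thinning a homogeneous envelope. `k = 0`
gives uniform engagement; any `k > 0` concentrates trials in the first
half of the session. The exponential form is a modeling choice (any
monotone decay would produce the same qualitative signature); it is
config-exposed through `k`. Initiations that arrive while the device is
busy (previous trial plus its inter-trial interval) are dropped, which
mildly thins the realized rate at high `lambda0`.

**Choice.** Given the layout in force, the probability of selecting a
task is a softmax over
`u_task + b_position(task's button) + gamma_task * t_norm + delta_task * session`,
with the middle position and the picture task as references -- exactly
the linear predictor of the preference model below, so utilities
recovered by the model are estimates of `u`.

**Touch accuracy.** With probability `p_ignore` a reach trial is
ignored. Otherwise the agent responds at latency
`motor_delay + U(0, jitter)`, aims at the target's true position at
touch time (perfect motion extrapolation), and lands with isotropic
Gaussian error of sd `sigma0 + sigma_v * v`, clipped to the background
region. Perfect extrapolation makes the hit probability available in
closed form, `1 - exp(-(d/2)^2 / (2 sigma^2))`, which the tests use as
an oracle; speed difficulty enters only through `sigma_v`. No
reaction-time data constrain the latency model, so it is a free
two-parameter family with defaults (0.8 s + up to 0.6 s) in the range
of primate touch responses.

**Default cohort.** `default_cohort()` emulates the reference study
population: 16 adult males in 7 social groups of 2--3 sharing devices
(group members' trials interleave on one session timeline; within-group
access contention is ignored), six weekly sessions of nominally 8 h.
Session durations vary uniformly on 7.65--8.35 h so that the
duration-controlled trend analysis has a real covariate to work with;
this keeps the 8 h average while staying narrower than the full range
reported for the original sessions. Every agent expects ~418 trials per
session (the base rate is rescaled so the *thinned* process has that
mean, via `engagement_rate_for()`), and the default decay `k = 0.25`
was chosen once so that the median normalized trial time sits near
0.47, the within-session decline the device's users observe; ten agents
prefer the static task and two the dynamic task by 2 logits, four are
indifferent, matching the preference mix such cohorts show. Touch
parameters (`sigma0 = 2` deg, `sigma_v = 0.08` deg per deg/s,
`p_ignore = 0.05`) give psychometric curves rising from roughly half to
near-certain hits across the size grid and dropping by ~0.3 across the
speed grid. Inter-animal variation in engagement *rate* is deliberately
not emulated (all agents share the expected count); the analyses under
test do not depend on it, and leaving it out keeps the cohort mean an
exact design quantity.

What passing recovery tests on these synthetic cohorts shows is that
the pipeline correctly inverts its own generative assumptions at the
study's scale -- not that real macaques satisfy those assumptions; in
particular the agent has no learning dynamics (the session slope
`delta` is a linear proxy), no satiety interaction between reward and
engagement, and no lapses in motion extrapolation.

## Engagement analysis

Trial initiation times are normalized by session duration; the median
of each animal-session's distribution says at which session proportion
the animal had done half its trials. Across animal-sessions the medians
are tested against 0.5 with a two-sided one-sample t-test.
Animal-sessions with zero trials never enter the log and are therefore
excluded from the median distribution (the natural reading of an
observed count below the full animal-by-session grid). The
across-session trend per animal is the first-order partial correlation
between trial counts and session index controlling for session
duration,
`r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, with
`t = r sqrt((n-3)/(1-r^2))` on `n - 3` df; the identity with the
residual-regression construction is a tested invariant. With fewer
than three sessions, or constant inputs (e.g. identical durations), the
statistic is undefined and reported as missing rather than silently
approximated.

## Task proficiency

Hit rate is `hits / (hits + failures)` -- ignored trials carry no touch
and are excluded from the denominator by default (`include_ignored`
exposes the alternative). The *adjusted* hit rate subtracts the
size-dependent chance level, an affine shift that makes performance
comparable across sizes and leaves within-size orderings untouched. For
the speed analysis, per-size adjusted rates are averaged with
trial-count weights within each speed, and the resulting 21-point curve
is correlated with speed (Pearson; 95% CI via Fisher z). The per-test
threshold is Bonferroni-corrected with the family size equal to the
number of animals analyzed -- 0.05/16 = 0.003 at the reference cohort
size. Cells of the size-by-speed heatmap with fewer than 5 scored
trials are masked (the reference analysis flags animals with
insufficient trials without stating a threshold; 5 per cell is the
package's choice, config-exposed), and the best cell per animal is the
argmax with ties broken toward smaller size, then smaller speed, so
reports are deterministic.

## Task preference: the Bayesian categorical model

Task choice is modeled as a hierarchical categorical (multinomial
logit) regression with the picture task as reference. For category
`k in {static, dynamic}`:

eta_k = b0_k + position effects + b_time,k z(time) + b_sess,k z(session)
+ random effects,  P(task) = softmax(0, eta_static, eta_dynamic).

How "the position of the button" enters a categorical model is
genuinely ambiguous; the package encodes, for each non-reference
category, the position of *that task's own button* in the trial's
layout (middle as reference). This conditional-logit-style coding makes
"probabilities at the middle position" well defined -- with all
position terms at middle, they contribute nothing -- and it is isolated
inside `build_design()` so an alternative coding has one home. Time of
day is hours since session start and session index is its rank, both
z-scored; covariates constant over the modeled trials are dropped with
a warning. Random effects comprise intercepts by animal, group, and day
(calendar session date -- distinct from the continuous session
covariate), and position/time/session slopes by animal and by group;
slope-by-day is not identifiable with one observation window per day.
Each (grouping factor, effect) pair is bivariate normal across the two
response categories with its own sds and correlation. Correlations
*between different effects* within a grouping factor are fixed at zero:
the across-category 2x2 correlation is the part of the maximal
structure that both matters for per-animal probability estimates and
admits an exact conjugate treatment; the rationale is sampler
exactness, discussed next. Priors are weakly informative: N(0, 1) on
intercepts, N(0, 0.5) on other fixed effects, Exponential(1) on
random-effect sds, and LKJ(2) on each correlation (for a 2x2 matrix the
LKJ(2) density is proportional to `1 - rho^2`, equivalently
`rho = 2 Beta(2,2) - 1`, which the sampler uses exactly).

**Sampling.** The posterior is explored by an exact Gibbs scheme built
on Polya-Gamma data augmentation: conditional on the other category's
predictor, the categorical likelihood in category k is binary-logistic
in `psi_k = eta_k - log(1 + exp(eta_other))`, and augmenting with
PG(1, psi) latent variables makes the full set of category-k
coefficients -- fixed and random jointly -- conditionally Gaussian. The
PG(1, z) draws use Devroye's alternating-series rejection sampler
(implemented in C++, validated against closed-form moments and the
infinite-series representation). Two further ingredients matter for
short-chain behavior:

* *Partial collapsing.* Each random-effect block's sd is updated from
  its conditional with the block's effects integrated out analytically
  (a small eigendecomposition per block), then the effects are redrawn
  exactly. This removes the classic funnel coupling between a scale and
  its effects that throttles naive Gibbs samplers for hierarchical
  models.
* *Composite iterations.* One stored iteration performs four full
  augmentation sweeps plus the hyperparameter updates, so successive
  stored draws are nearly independent.

Because every update is a draw from an exact conditional (Gaussian,
inverse-eigenvalue form, or slice sampling for the sd/correlation
triples), the scheme has no divergent transitions -- that diagnostic
belongs to Hamiltonian samplers; the fit reports `divergences = 0` by
construction and convergence is judged on split-chain R-hat (each chain
halved, between/within ratio), computed by `split_rhat()` with the
threshold 1.01. An over-relaxed variant of the updates exists behind
`control = list(or_alpha = ...)` but is off by default: measured on
this model class it slows exploration of prior-dominated ridge
directions (day and group effects collinear with the session covariate)
more than it suppresses chain-mean noise.

The default run configuration is 2 chains of 1000 iterations (500
warm-up), sized for desk-scale verification; 4 chains of 2500 (1000
warm-up) is the reported-run configuration of the original toolchain
and is what the CLI's `--mcmc-scale full` selects. Parameter recovery,
R-hat, and verdict operating characteristics at the desk scale are
exercised in the test suite, with a long-run JAGS fit as an independent
oracle for the fixed-effects core.

**Inference.** Per-animal task probabilities are the per-draw softmax
with covariates at 0 (the z-scale mean), all position terms at the
neutral middle, the animal's own and its group's random intercepts
included, and the day intercepts at their per-draw average. The last
choice matters: the fixed intercept and the day intercepts are only
jointly identified, so predicting at a hypothetical day with effect 0
would inject that ridge's posterior variance into every per-animal
interval -- visibly so when only a few days are observed; "an average
observed day" is the estimand the per-animal intervals describe. An animal shows
*evidence* for task i over task j when the lower bound of P(i)'s 95%
credible interval exceeds the upper bound of P(j)'s; the verdict is the
highest-posterior-mean task among those with evidence over at least one
other task, else "none". This interval-separation rule is conservative
by construction, which the verdict-recovery tests quantify (indifferent
agents are labeled "none" at high rates; preferring agents need a
utility gap on the order of 2 logits and a few hundred trials).

## Numerical and scale choices

Simulation sizes in the test suite are chosen to bound Monte-Carlo
error well below the tested effects: binomial checks use 3-sigma bands
at n between 2 000 and 10^6; calibration rates use 1 000 (type-I at
alpha = 0.05) or 2 000 (at alpha = 0.003) replicates; kinematics
tolerances are 1e-9 (speed conservation) and 1e-6 deg (integration
agreement), both limited only by floating-point accumulation. The
engagement calibration runs on the study-condition scale (16 animals,
6 sessions, 8 h, ~418 trials per animal-session); verdict recovery
uses 6 agents with 400 trials each, the smallest configuration at
which the interval-separation rule has headroom. Degenerate inputs
fail loudly by design: empty sessions, zero-variance medians, constant
covariates, unknown sizes, and all-masked heatmaps each have a defined
error or missing-value path exercised by the tests.

## Known limitations

* The agent's motion extrapolation is perfect, so speed difficulty is
  purely a noise-scale effect; real animals also mistime interceptions.
* Within-group device contention is ignored; group members' processes
  are independent and merged by time.
* The chance-level discrepancy of the reference apparatus is carried as
  a calibration table, not explained.
* The categorical model fixes between-effect correlations at zero (see
  above); fits seeking the maximal brms-style structure will estimate
  additional correlations this package deliberately does not.
* `delta` (session slope) is a linear stand-in for learning; cohorts
  with genuine acquisition curves would need a richer agent.
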