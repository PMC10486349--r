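# mcisim

Simulation and analysis of a touchscreen **multiple-choice interface
(MCI)** for captive rhesus macaques. On the device's home screen three
buttons lead to three tasks the animal freely chooses between, trial by
trial: a *static reach* (touch a stationary disc for 0.37 mL of fluid),
a *dynamic reach* (touch a disc bouncing at 10–30 deg/s), and an
unrewarded 5 s *picture viewing*. Logs from such sessions support three
questions — how much and when animals engage, which task they prefer,
and how proficiently they perform — and this package implements the
full loop for all three: a deterministic-given-seed task engine, a
generative behavioral agent with known ground-truth parameters, and the
analysis stages, so the whole method can be exercised end to end
without animals or hardware.

The statistical core:

* **Engagement** — trial times normalized to session duration; the
  median of each animal-session distribution m tested against 0.5
  (two-sided one-sample t-test), and an animal-wise first-order partial
  correlation r<sub>xy·z</sub> between trials and session index
  controlling for session duration.
* **Task preference** — a hierarchical Bayesian categorical
  (multinomial-logit) model: for k ∈ {static, dynamic} (picture the
  reference), η<sub>k</sub> = β<sub>0k</sub> + position effects +
  β<sub>t,k</sub> z(time) + β<sub>s,k</sub> z(session) + random
  intercepts (animal, group, day) and slopes (animal, group), with
  priors N(0,1) / N(0,0.5) / Exponential(1) / LKJ(2) and
  P(task) = softmax(0, η<sub>static</sub>, η<sub>dynamic</sub>).
  Fitted by an exact Pólya–Gamma Gibbs sampler with partially collapsed
  scale updates; convergence judged on split R-hat ≤ 1.01. An animal
  shows a *preference verdict* when one task's 95% credible interval
  lies entirely above another's.
* **Proficiency** — hit rates corrected by the size-dependent *chance
  level* (stimulus-to-background surface ratio; the device's
  calibration table 7.33%…30.24% for 5…10 deg is built in), per-speed
  adjusted hit-rate curves, Pearson speed correlations with Fisher-z
  CIs at the Bonferroni-adjusted α = 0.05/16 ≈ 0.003, and the best
  size–speed cell per animal.

## Worked example

Simulate a small cohort — six animals in two groups, three of them with
a 2-logit preference for the static task — and run the three analyses:

```r
library(mcisim)
set.seed(7)

agents <- lapply(1:6, function(i) {
  u <- c(static = 0, dynamic = 0, picture = 0)
  if (i <= 3) u["static"] <- 2          # ground-truth preference
  agent_profile(sprintf("a%02d", i), if (i <= 3) "G1" else "G2", u = u,
                lambda0 = engagement_rate_for(120, 0.25, 4 * 3600),
                k = 0.25)
})
sim <- simulate_cohort(cohort_spec(agents, n_sessions = 3),
                       session_config(session_duration_s = 4 * 3600))

analyze_engagement(sim$log)
#> Engagement summary
#>   18 animal-sessions; mean trials/session 228.9
#>   median-of-medians 0.488; shift test t = -2.69, df = 17, p = 0.01558

analyze_proficiency(sim$log, table = xbi_chance_table())
#> Proficiency summary
#>   6 animals, per-test alpha 0.008333 (Bonferroni)
#>   significant speed modulation: 1; insufficient data: 0
#>   pooled best cell: size 10 deg at 12 deg/s (adj. rate 0.698)

pref <- analyze_preference(sim$log, chains = 2, iter = 1000,
                           warmup = 500, seed = 1)
pref
#> Task-preference analysis
#> Bayesian categorical task-preference model (Polya-Gamma Gibbs)
#>   2 chains x 1000 iterations (500 warm-up); 129 parameters
#>   max R-hat 1.005; divergences 0; converged
#>   verdicts: none=3  static=3
```

Reading the output: the cohort was generated with within-session decay
k = 0.25, so animals front-load their trials -- the animal-session
medians center below 0.5 and the shift test rejects uniform engagement
(t = -2.69, p = 0.016). In the proficiency stage this small
three-session cohort gives only one animal enough dynamic trials to
clear the Bonferroni bar (alpha = 0.05/6) on its speed correlation;
the operating characteristics of that test at realistic trial counts
(~0.3% type-I at alpha = 0.003, >= 90% power against a 0.3
hit-probability drop) are quantified in the acceptance suite. The
preference model returns the verdict `static` for exactly the three
agents given the 2-logit utility gap and `none` for the indifferent
three, with all split R-hat values at or below 1.01 and -- the sampler
being conjugate Gibbs -- zero divergent transitions. Per-animal
posterior probabilities live in `pref$probs`; animal `a01` gets
P(static) = 0.78 [0.74, 0.82] against P(picture) = 0.11 [0.09, 0.13] --
separated intervals, hence the verdict -- while the indifferent `a05`
has all three intervals overlapping 1/3.

A command-line front end wrapping the same functions lives at
`inst/cli/mci.R`:

```sh
Rscript inst/cli/mci.R simulate --seed 1 --out log.csv --truth truth.csv
Rscript inst/cli/mci.R analyze engagement  --log log.csv --out results
Rscript inst/cli/mci.R analyze proficiency --log log.csv --out results --chance-table
Rscript inst/cli/mci.R analyze preference  --log log.csv --out results --mcmc-scale desk
Rscript inst/cli/mci.R report --results results --out report
```

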