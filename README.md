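# tempodisc

Simulation and estimation pipeline for binary intertemporal-choice
experiments, built for studying **delay discounting** and **choice
consistency** as predictors of clinical outcomes (here: smoking relapse
after a quit attempt).

People devalue rewards that arrive later. The standard one-parameter
account is the hyperbolic value function

    V(A, D) = A / (1 + k·D)

(`A` amount in €, `D` delay in days, `k` the discount rate in 1/days),
combined with a softmax decision rule

    P(choose A) = exp(β·V_A) / (exp(β·V_A) + exp(β·V_B))

whose inverse temperature `β` (1/€) measures how deterministically
choices track value. But `k` and `β` do not exhaust individual
differences: this package's centerpiece is **var(k)** — the width of a
sequentially updated Bayesian posterior over log k after a choice
sequence — an index of choice *inconsistency* ("fickleness") that rises
when a subject's choices cannot be reconciled with any single discount
rate.

The package implements the full measurement and analysis chain:

1. **Staircase calibration** (`run_staircase`, `indifference_points`,
   `fit_hyperbolic_k`): a 50-trial titration (immediate 20 €, first
   delayed offer 40 €, five delays, halving steps) yielding per-delay
   indifference points and a least-squares pre-scan `k`.
2. **Individualized task design** (`build_schedule`): a 90-trial offer
   set tailored to the subject's `k` so that half the offers beat the
   immediate amount, the mean subjective value is 30 € for everyone, and
   the largest value is twentyfold the smallest.
3. **Sequential Bayesian estimation** (`estimate_sequence`): a
   discretized joint posterior over (log k, log β), updated trial by
   trial, returning `k_hat`, `beta_hat`, and the consistency index
   `var_k`.
4. **Synthetic cohorts with planted truth** (`sample_cohort`,
   `simulate_sessions`, `sample_relapse`): three groups with realistic
   (log k, log β, FTND) distributions and exponential relapse times with
   planted proportional-hazards effects (FTND HR 1.24/point, var(k)
   HR 2.18/unit, no k effect), censored at 180 days.
5. **The statistical stage** (`compare_groups`, `longitudinal_tests`,
   `cox_relapse`, `recovery_report`): Shapiro-gated t / Mann-Whitney
   contrasts, mixed ANOVA and signed-rank longitudinal tests, and Cox
   survival models of relapse.

The methods vignette
(`vignettes/choice-consistency-pipeline.Rmd`) documents the models,
the design conventions, and what the synthetic validations do and do not
show.

## Worked example

```r
library(tempodisc)

agent <- agent_params(k = 0.02, beta = 1.5)   # simulated subject
cal <- calibrate_agent(agent, seed = 42)      # pre-scan staircase
print(cal$curve)
#> indifference points (EUR):
#>  delay    point one_sided
#>     10 23.45703     FALSE
#>     30 31.95312     FALSE
#>     60 46.89453     FALSE
#>    120 73.78906     FALSE
#>    180 91.71875     FALSE
cal$k_prescan
#> [1] 0.02117995

sched <- build_schedule(cal$k_prescan, seed = 43)
print(sched)
#> task schedule: 90 trials, 5 delays; mean value 30.00 EUR, max/min ratio 20.00
#> immediate amount (hidden): 14.07 EUR; design k = 0.02118 /day

set.seed(44)
choices <- simulate_choices(sched$trials, agent)
est <- estimate_sequence(sched$trials, choices,
                         k_center = cal$k_prescan, trajectory = FALSE)
print(est)
#> estimate: log k = -3.936, log beta = 0.186, var(k) = 0.0776, var(beta) = 0.2260 (90 trials)
```

Reading the output: the staircase's indifference points rise with delay
exactly as a hyperbolic discounter's should (e.g. ~47 € at 60 days ≈
20·(1 + 0.021·60)); the fitted pre-scan rate 0.0212/day sits next to the
agent's true 0.02/day. The schedule satisfies its design constraints
exactly. After 90 choices the posterior mean log k = −3.94 is close to
the truth (log 0.02 = −3.91), and the small var(k) = 0.078 reflects a
reasonably consistent (β = 1.5) agent.

## The analysis workflow

The `analysis/` scripts run the study end to end on a synthetic cohort
(103 subjects: 29 non-smokers, 30 occasional, 44 treatment-seeking
smokers), writing tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R   # cohort + full measurement chain
Rscript analysis/02_group_contrasts.R   # group and outcome contrasts
Rscript analysis/03_survival.R          # Cox model of relapse, life table
Rscript analysis/04_recovery.R          # recovery of parameters and planted HRs
```

With the default planted effects, the pattern at study scale (n = 44
smokers) mirrors what the generator encodes: FTND predicts relapse,
measured var(k) carries a planted hazard that is recovered cleanly at
n = 500 (stage 4 reports a mean refit HR ≈ 2.2 against the planted
2.18), and log k predicts nothing.

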