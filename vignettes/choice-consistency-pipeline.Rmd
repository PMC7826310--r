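---
title: "Measuring delay discounting and choice consistency: models, design, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring delay discounting and choice consistency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempodisc)
```

## The behavioral model

A subject choosing between an immediate amount and a larger delayed amount
is modelled by two parameters. The hyperbolic value function

$$V(A, D) = \frac{A}{1 + kD}$$

devalues an amount $A$ euros delayed by $D$ days at rate $k$ (1/days):
larger $k$ means steeper discounting. Choices follow a two-option softmax,

$$P(\text{choose } A) = \frac{e^{\beta V_A}}{e^{\beta V_A} + e^{\beta V_B}},$$

where the inverse temperature $\beta$ (1/euro) measures how
deterministically the higher-valued option is taken: $\beta = 0$ is coin
flipping, $\beta \to \infty$ is strict value maximization. $\beta$ is
applied to values in euros, not to rescaled values. Across people both
parameters are right-skewed and approximately lognormal, so everything
downstream works on their natural logs; `agent_params()` stores both
scales and clamps $\log\beta$ at $-20$ so that $\beta = 0$ (a legal
random agent) remains representable.

Beyond $\beta$, the package computes a second, complementary consistency
index: **var(k)**, the width of the posterior distribution over $\log k$
after a choice sequence (below). $\beta$ is a fitted slope; var(k) is a
property of the evidence — it grows when choices are hard to reconcile
with any single discount rate.

## Staircase calibration

The pre-scan calibration titrates per-delay indifference points. A fixed
immediate amount (20 EUR) is paired with a delayed amount starting at
40 EUR; five delays (10, 30, 60, 120, 180 days) are presented in blocks
of 10 trials (50 analysis trials), preceded by 3 practice trials that are
excluded from every estimate. After a "delayed" choice the next delayed
amount falls by half the current delayed-immediate difference; after an
"immediate" choice it rises by the same half-difference. On a monotone
path the offer difference therefore halves every trial
($20 \times 2^{-(n-1)}$ EUR after $n$ trials), and in general the offers
bracket the indifference amount $20(1 + kD)$ for a value-maximizing
agent.

Numerical conventions (the procedure itself does not fix them):

* **Indifference point** = mean of the maximum delayed amount rejected
  and the minimum delayed amount chosen.
* **One-sided blocks.** A block with no rejections shows no measurable
  discounting at that delay: the point is the immediate amount. A block
  with no acceptances extrapolates half a step beyond the last offer.
* **Clamp.** Titrated amounts never fall below immediate + 0.01 EUR.
* **Block order** is ascending by default and configurable; amounts are
  kept at full float precision internally.

The pre-scan discount rate `k_prescan` is the bounded one-dimensional
least-squares fit of $k$ to the points (searched on the log axis over
$[10^{-5}, 10]$ /day, wide enough to enclose any plausible human value
with several SDs of margin). Flat points at the immediate amount drive
the fit to the lower bound — no discounting — and raise a warning flag.

## Individualized offer design

The 90-trial task is built around each subject's `k_prescan` so that
three constraints hold by construction:

1. half the offers are more valuable than the immediate amount and half
   less, so a subject behaving like the design $k$ chooses the immediate
   reward in about half the trials;
2. the mean subjective value of all offers is 30 EUR for every subject;
3. the largest subjective value in the set is twentyfold the smallest.

For each of the 5 delays, 9 below-immediate values come from
$V_d = V_0 (1 + kDc) / (1 + kD)$ with
$c \in \{0.10, 0.15, \ldots, 0.50\}$ — a form whose delayed amounts
$A = V(1 + kD)$ always remain nominally above the immediate amount — and
9 above-immediate values divide the span from $V_0$ up to the ceiling
into equidistant categories. Design decisions where the construction is
open:

* The twentyfold ceiling is **global**: it is 20 times the single
  smallest value of the whole set (the 180-day, $c = 0.1$ entry), the
  only reading under which the max/min ratio of the full set is exactly
  20.
* Equidistant upper categories span $(V_0, V_{\max}]$ — inclusive of the
  ceiling, exclusive of $V_0$ — with step $(V_{\max} - V_0)/9$.
* The pre-standardization base $V_0$ is 20 EUR (the calibration immediate
  amount). All 90 values and $V_0$ are then rescaled by the single factor
  $30/\bar V$; rescaling values (rather than amounts) first keeps the
  ratio constraint exact, and the rescaled $V_0$ becomes the subject's
  adapted immediate amount, carried in its own column because it is not
  shown during the task.

`build_schedule()` shuffles trial order and randomizes screen side under
the supplied seed; the multiset of offers is seed-invariant.

## Sequential Bayesian estimation and var(k)

`estimate_sequence()` carries a joint posterior over $(\log k, \log\beta)$
on an equally spaced grid (default $101 \times 101$ over
$\log k \in [-9, 0]$, $\log\beta \in [-5, 3]$ — bounds leave $\ge 4$ SD of
margin around plausible population means). Equal spacing on the **log**
axes honors the lognormal population support. The prior is the outer
product of independent discretized normals: the $k$-prior is centered at
`k_prescan` with SD 1.5 log units, the $\beta$-prior at $\log\beta = 0$
with SD 1.5 — deliberately diffuse, since the calibration session carries
no direct information about consistency. All prior hyperparameters are
exposed.

Each observed choice multiplies every cell by its softmax likelihood and
renormalizes. Numerics: likelihoods are accumulated in log space with
max-subtraction before exponentiation, so 90-trial products cannot
underflow; a fully underflowed grid (impossible with strictly positive
softmax probabilities, but guarded) raises an error rather than
renormalizing zeros. Because the update is a product of per-trial
likelihoods, the final posterior is invariant to trial order and equal to
a one-shot batch update — the central correctness oracle in the test
suite. Missed responses are dropped before estimation.

Summaries are discrete moments of the marginals: `k_hat` and `beta_hat`
are posterior means of $\log k$ and $\log\beta$, and `var_k` is the
posterior variance of $\log k$ (a natural-scale option exists; the log
axis is the default because estimation lives there and observed var(k)
magnitudes are consistent with log-scale variances).

### How var(k) behaves

Under consistent choices the posterior contracts, so var(k) falls over
the task; a value-incongruent choice forces probability mass toward
previously disfavored parameter regions. Two regimes are worth
distinguishing, both verified numerically in the test suite:

* **While the posterior is still forming** (roughly the first third of a
  session), an incongruent choice strictly inflates var(k) — the
  "fickleness" mechanism: mass spreads toward low-$\beta$ and
  shifted-$k$ cells that are individually broad.
* **After a long, perfectly consistent run**, the posterior is a tight
  ridge in $(k, \beta)$, and a single strongly incongruent choice acts as
  *informative* evidence for a different discount rate: it relocates the
  $k$ marginal and can narrow it. Real sessions, which carry softmax
  noise throughout, keep the posterior wide enough that inconsistency
  accumulates into larger final var(k); across simulated heterogeneous
  cohorts the Spearman correlation between final var(k) and true
  $\log\beta$ is about $-0.6$ — random ($\beta = 0$) agents always end
  with wider posteriors than matched consistent agents.

## The synthetic cohort

`sample_cohort()` draws a three-group population — non-smokers,
occasional smokers, treatment-seeking smokers (29/30/44 by default) —
with group normals on $\log k$ (means $-4.38$/$-4.06$/$-3.98$, SDs
1.2-1.4) and $\log\beta$ (means $-1.28$/$-0.65$/$-1.01$, SDs 1.4-1.6),
chosen to emulate a treatment-seeking smoker cohort with matched
controls. FTND (nicotine-dependence score, 0-10) is a rounded truncated
normal (smokers: mean 5.0, SD 2.0; occasional: 0.1, 0.4; non-smokers 0);
FTND and discounting are independent by default, since no dependency
structure is established, with correlation exposable through the specs.

Relapse times are exponential (constant hazard) with log-linear effects
of measured covariates:

$$\lambda_i = \lambda_0 \exp\{b_F (\mathrm{FTND}_i - 5.0) +
  b_V (\mathrm{var}(k)_i - 0.3) + b_k (\hat k_i + 3.98)\},$$

censored at 180 days, with relapse within 30 days defining early
relapsers. Defaults plant $b_F = \ln 1.24$, $b_V = \ln 2.18$, $b_k = 0$:
consistency and dependence drive relapse, discounting itself does not, so
the downstream Cox stage has a known truth to recover. The hazard acts on
*measured* var(k) (the estimator's output), because that is the quantity
a study can use as a predictor. Design notes:

* The linear predictor is centered at reference covariate values (FTND
  5.0, var(k) 0.3, $\log k$ $-3.98$) so $\lambda_0$ keeps a marginal
  interpretation; the default $\lambda_0 = -\ln(1 - 19/44)/30$ makes
  about 43% of a reference cohort relapse within the window, and
  `calibrate_baseline()` solves the exponential closed form exactly for
  any covariate mix.
* Constant hazard is the simplest member of the proportional-hazards
  family the Cox stage assumes; any PH generator would do.

Two measurement modes feed the survival stage. `simulate_sessions()` runs
the full chain (staircase, schedule, choices, posterior) per subject and
is used wherever estimator behavior is itself under test. For large
replicate designs (hundreds of cohorts of $n = 500$),
`attach_synthetic_estimates()` draws the measured quantities directly:
`k_hat` as latent $\log k$ plus noise (SD 0.25, matching full-chain
recovery error), and var(k) lognormal with marginal moments
(mean ~0.32, SD ~0.6) and a built-in negative $\log\beta$ slope mirroring
the full chain's inverse relation. This keeps the survival validations at
desk scale while preserving the covariate structure that matters to them.

**What the generator does not emulate:** session-to-session drift,
reaction times, trial-level attention lapses, any FTND-discounting
dependence, and non-proportional or time-varying hazards. Passing tests
therefore certify the computational chain and the statistical stage's
operating characteristics under the planted model — not the empirical
claims themselves on human data.

## The statistical stage

* `compare_groups()` screens each group with Shapiro-Wilk at
  $\alpha = 0.05$; both normal → Student's t (equal variances, Cohen's
  d), otherwise Mann-Whitney U with effect size $r = |Z|/\sqrt{N}$, $Z$
  from the tie-corrected normal approximation. The p-value is exact for
  $\min(n) \le 20$ without ties, continuity-corrected asymptotic
  otherwise. The gate can be forced either way for reproducibility.
* `longitudinal_tests()` runs a mixed ANOVA (time x group, subject error
  stratum) for $\log k$ and a Wilcoxon signed-rank test for var(k), with
  listwise deletion and a no-change sentinel when all paired differences
  are zero.
* `cox_relapse()` fits `survival::coxph` with Efron tie handling over a
  180-day horizon, warns below 10 events per covariate, and flags
  unstable fits. Raw var(k) is the default coding.
* No multiple-testing correction is applied by default, matching common
  single-hypothesis reporting in this literature; `stats::p.adjust` can
  be applied to the returned p-values where a family-wise view is wanted.

## Validation problem sizes

The test suite validates: exact design constants (90 trials, 18 per
delay, 9/9 split, mean 30 EUR, twentyfold ratio, 50-trial calibration);
sequential-equals-batch and permutation invariance at $10^{-10}$ on the
full grid; parameter recovery (median $|\hat k - \log k| \le 0.3$ over
100 full-chain subjects); var(k) ordering of random vs consistent agents
(100 paired seeds); type-I error of the Mann-Whitney and Cox stages
within binomial bounds of 5% over 1000 null replicates; and recovery of
the planted var(k) log-hazard $\ln 2.18$ to a mean HR in $[1.9, 2.5]$
over 100 cohorts of $n = 500$. These sizes were chosen so each property
is measured with adequate Monte-Carlo precision while the whole suite
stays quick to run.

## Known limitations

* The estimator assumes the hyperbolic form; exponential or
  quasi-hyperbolic discounting, probability weighting and risk attitudes
  are out of scope.
* var(k) depends on the grid and prior hyperparameters; comparisons
  across studies require fixing them.
* The grid posterior is exact only up to discretization; 101 points per
  axis put the discretization error well below the Monte-Carlo noise of
  a 90-trial session.
* Group moments and planted hazards are population-level emulations, not
  fitted to any individual-level data.
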