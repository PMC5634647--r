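---
title: "Models and methods in flexmb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in flexmb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the modelling choices behind flexmb: the task
environment, the learning models, the hierarchical fitting machinery, and
the places where the design was genuinely open and we had to commit to one
reading. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The task environment

`task_config()` describes a 600-trial session of three 200-trial blocks.
Trials start at the first level `S0` with probability 0.5 or at a
second-level state `S1`/`S2` (0.25 each). First-level actions map
deterministically onto second-level states; second-level states map onto
terminal states `S3`/`S4` under one of two complementary contingencies,
which flips after a number of trials drawn uniformly from the active
block's range (3–6, 7–10 or 11–14; the fast/medium block order
distinguishes the two counterbalancing groups, the slow block is always
third).

**Payoff walk.** The high payoff starts from N(0.5, 0.2) truncated to the
bounds, takes a per-trial Gaussian increment of sd 0.15, and *reflects* at
the bounds; the low payoff is always 1 minus the high payoff. A
mean-reverting walk toward 0.5 would be an equally natural design; we
chose the plain reflected walk as the least-structured option and note
that its stationary distribution spreads payoffs over the whole unit
interval, so the payoff of the nominally "high" state crosses 0.5
regularly. That observation matters below.

**Event timing.** A contingency flip is applied at trial onset, so the
flip trial itself already exhibits the new mapping (the subject always
experiences the new structure). High/low reward assignments swap at trials
that are multiples of `reward_flip_period` (40, 80, …, 600 — five per
block), also at onset. The two kinds of change never coincide: a scheduled
flip landing on a multiple of 40 is redrawn from the same gap range. Two
degenerate corners need care: a proposed flip that crosses a block
boundary is redrawn from the *new* block's range (so every realised gap is
legal for the block its flip lands in), and a width-zero gap range such as
(3, 3) can make redrawing futile (trial 120 is a multiple of both 3 and
40), so after 100 failed redraws the flip is shifted by one trial —
consecutive integers are never both multiples of 40.

**Trial indexing** is 1-based; `block = ceiling(trial / 200)`. The
simulator never produces missed trials, but the CSV schema allows an empty
`first_choice` (and empty transition fields) so partial real logs load;
such trials contribute no likelihood and no learning but keep their place
in the sequence.

## The learning systems

Both systems value first-level actions on the [0, 1] reward scale and all
tables start at 0.5, the indifference point of the mirrored scale — an
unbiased start; the model-based transition table starts at mapping A.

**Model-free.** A TD(λ) Q-learner. On a trial through second-level state
$s$ with terminal reward $r$: $\delta_2 = r - Q_{MF}(s)$ and
$Q_{MF}(s) \mathrel{+}= \alpha_{MF}\,\delta_2$. If the trial started at
`S0` with action $a$, the first-level value receives
$\alpha_{MF}(\delta_1 + \lambda\,\delta_2)$ with
$\delta_1 = Q_{MF}(s) - Q_{MF}(S0, a)$ computed *before* the second-level
update (first-level reward is zero). The compact update rule
"$Q \mathrel{+}= \alpha\lambda\delta$" is often written without
distinguishing the levels; resolving it this way is the only reading
consistent with the standard TD(λ) limits — at λ = 0 first-level actions
learn only through second-level values, at λ = 1 they are credited
directly with the terminal reward.

**Model-based.** Each observed second-to-terminal transition identifies
one of the two complementary mappings, and *both* rows of the transition
table move toward it — fully under the standard model (rate 1), partially
under the free-transition-rate variant ($\alpha_{T}$). The subjective
reward of the visited terminal state follows the delta rule
$R \mathrel{+}= \alpha_{MB}(r - R)$ — the convergent form that moves the
estimate toward the observed reward (the opposite sign, sometimes seen in
compact write-ups of such updates, diverges).

**Fictive (mirrored) updates.** Because the two second-level routes and
the two terminal states carry complementary payoffs, updating a visited
entry licenses setting its unvisited counterpart to one minus the new
value. We mirror the second-level $Q_{MF}$ values and the terminal $R$
values; first-level action values are updated only through their own
prediction errors. An alternative reading also writes $1 - Q$ into the
unchosen first-level action directly; the second-level mirror induces the
same preference reversal one trial later, and we kept the narrower scope
(the fictive argument concerns outcomes, not action propensities). The
`fictive = FALSE` ablation switches all mirrors off.

**Choice.** The hybrid value is
$w_{MB} Q_{MB} + (1 - w_{MB}) Q_{MF}$ per first-level action; a stay bias
is added *transiently at decision time* to the most recently chosen
first-level action (across any intervening forced trials — it is never
written into the stored values), and an overflow-safe softmax with inverse
temperature β yields the choice probabilities. Control hybrids replace the
MB/MF pair by two same-kind systems with learning rates fixed at 0.25 and
0.75, mixed by the same free weight.

### Parameters, units, defaults

| parameter | range | default | role |
|---|---|---|---|
| `wMB` | [0, 1] | 0.56 | MB weight (scalar, per block, or per frequency class); the default is a mid-range weight at which both strategies visibly contribute |
| `alpha_MF`, `alpha_MB` | [0, 1] | 0.5 | learning rates (value units per prediction-error unit) |
| `beta` | ≥ 0 | 5 | softmax inverse temperature (1/value units) |
| `lam` | [0, 1] | 0.5 | eligibility trace |
| `stay_bias` | ℝ | 0.2 | additive decision-time bonus (value units) |
| `alpha_MB_transition` | [0, 1] | 1 | transition learning rate; fixed at 1 except in the free variant |

The non-weight defaults are mid-range values chosen once as a realistic
operating point — clearly stochastic but reward-sensitive behaviour with
visible perseveration; they double as the reference values held constant
in the recovery grid, and every function that uses them accepts
overrides.

## Behavioural analyses

**Stay probability** is the probability of choosing the first-level action
leading to the same second-level state as visited on the previous trial.
An analysis trial must start at `S0` with a recorded choice and have at
least two predecessors; the main variant conditions on a previous trial
that started at the second level (only those dissociate the systems — no
first-level action was taken under the possibly-new contingency), the
supplementary variant on a previous first-level trial. Cells cross the
previous trial's reward (high/low) with whether its transition had changed
relative to the trial before. Trials following a missed trial are
ineligible. Empty cells are reported with count 0 and an undefined
probability, never as probability 0.

One definitional point: we classify the previous trial's reward as "high"
when the *received payoff* exceeded 0.5 — i.e. it was the larger of the
two complementary payoffs in force. Classifying instead by which terminal
state carries the nominal "high" label is not equivalent, because the
payoff walk crosses 0.5 and the labelled state then pays the smaller
amount; the label-based definition washes out the very signatures the
index is designed to show. The same value-based definition drives the
high-reward-choice summary in `performance_summaries()`.

**ANOVA.** `condition_anova()` runs a two-way ANOVA (reward × contingency)
on the four cell means per subject. The default treats cells as
independent observations — with 16 subjects that yields the F(1, 60)
layout — and a repeated-measures variant (`design = "within"`) partitions
subject variance instead; both are standard for this design, so both are
provided. Subjects with undefined cells are excluded with a message.

## Hierarchical fitting

`fit_em()` implements mixed-effects EM with a *diagonal* Gaussian group
prior over transformed parameters: logit for [0, 1] parameters, log for β,
identity for the stay bias (so natural-scale bounds hold by construction
and the Gaussian group assumption is respected). The E-step maximises each
subject's log posterior by BFGS from `n_restarts` draws from the current
prior (default 5; the previous MAP is always added as a warm start from
iteration 2), with the Laplace covariance taken from a finite-difference
Hessian at the optimum (`stats::optimHess`); a non-positive-definite
Hessian falls back to a small flat covariance. The M-step re-estimates
each group mean as the mean of the MAPs and each variance as the second
moment of MAP² + Laplace variance minus the squared mean (`m_step =
"laplace"`, the default; `"map"` drops the covariance term — both are
standard mixed-effects updates, so both are implemented). Variances are floored at 1e-4 and EM stops when every group
mean moves less than 1e-3 on the transformed scale, or at 50 iterations
(the result is then flagged unconverged but returned).

**iBIC.** The marginal likelihood of each subject under the fitted group
prior is estimated by Monte Carlo (default 2000 draws per subject, seeded;
the standard error is returned so the count can be raised), and
`iBIC = −2 Σ log p̂ + k log n` with `k` the number of group
hyperparameters (two per free parameter) and `n` the total count of choice
trials. **Exceedance probabilities** come from the standard random-effects
variational scheme over model frequencies (symmetric Dirichlet prior,
count 1), with the exceedance itself estimated by sampling the Dirichlet
posterior; the per-subject evidence fed in is the same Monte-Carlo
integrated likelihood, so one evidence definition serves both comparison
criteria.

## Validation machinery

**Parameter recovery.** `recovery_grid()` varies one block's weight at a
time over a grid (11 values 0, 0.1, …, 1 by default; the acceptance script
uses 5 for runtime), holding the other two blocks at the reference weight
— varying one block at a time keeps each setting interpretable as a single
recovery probe while the off-grid blocks provide a stable context.
Each setting is a fresh 16-subject cohort; `run_recovery()` refits the
three-block hybrid and correlates true against median-recovered weights
per block and overall.

**Permutation tests.** For block-wise weight differences, each subject's
600 trials are randomly relabelled into three equal pseudo-blocks — labels
only, the trial sequence and learning dynamics are untouched; the labels
decide which weight component governs each trial's choice probability —
the model is refitted, and the across-subject fraction of subjects with
the later-block weight larger is recomputed. For frequency-wise
differences, each subject's counterbalancing group (which fixes the
block-to-frequency mapping) is reassigned at random. The one-tailed
p-value uses the add-one correction `(count + 1)/(n_perm + 1)`, which is
exactly super-uniform under the null; the two-tailed Hellinger statistic
compares the across-subject distributions of the two weights, either by
the Gaussian closed form on moment-matched fits (default) or by a
shared-histogram empirical estimator; the parametric form is smoother at
small N, the empirical form assumes less, so both are available. The
default permutation count is 100
(each permutation is a full refit); tests and examples reduce it.

## What the generator does and does not emulate

The synthetic cohorts reproduce the design's standard conditions: 16 subjects split
8/8 over the two block orders, 600 trials each, the contingency-flip
schedule, the complementary drifting payoffs, and the 40-trial
reward-assignment swaps. They do not emulate response times, timeouts or
missed trials, practice/training phases, stimulus-position randomisation,
or any within-subject parameter drift — agents hold fixed parameters for a
session. Passing the simulation-based tests therefore shows that the
pipeline is *self-consistent* (it recovers what it generates, and the
qualitative MF/MB signatures follow from the model structure), not that
human data would be fit equally well.

## Problem sizes and numerical choices in the shipped checks

The test suite runs the qualitative stay-probability signatures at 1000
agents per strategy, the recovery check and acceptance script on the
reduced 5-value grid (15 settings × 16 subjects, 2 restarts, 12 EM
iterations), and the permutation null calibration on 20 replicates of
6-subject, 300-trial cohorts with 9 permutations each — sizes chosen so
the whole suite completes in minutes on one CPU while leaving each check
enough power to be meaningful. The likelihood floor is 1e-300 per choice
probability; the E-step objective returns 1e10 for non-finite values so
BFGS retreats instead of crashing.

## Known limitations

- The diagonal group prior ignores parameter correlations by design; the
  free-transition-rate variant is known to induce strong correlations and
  is provided for completeness, not as the default.
- Recovery quality is reported as correlation; hierarchical shrinkage
  biases extreme weights toward the group centre, which the correlation
  criterion tolerates but an absolute-error criterion would not.
- The Monte-Carlo iBIC is noisy at small sample counts; use the returned
  standard error before comparing close models.
- `condition_anova()`'s default between-cell design matches the reported
  degrees of freedom but treats within-subject cells as independent; for
  inference on real data the repeated-measures variant is the safer
  choice.
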