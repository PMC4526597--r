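---
title: "Models and methods: simulating and analysing outcome devaluation in the two-step task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

habitlearn simulates sequential two-step decision tasks with post-training
outcome devaluation and implements the analyses that connect trial-by-trial
learning to devaluation sensitivity: the trial-lagged stay-probability
regressions, the subject-level model-based and model-free indices, and
likelihood-based estimation of a hybrid reinforcement-learning agent with a
group-level slope linking the model-based weight to devaluation behaviour.
This vignette documents the models, the generator conventions, the tunable
parameters and the numerical choices, so that what the tests and the
acceptance script compute can be read against an explicit account of what
is being simulated.

## The task environment

Two variants are provided by `task_config()`.

* **Two-game variant (`"exp1"`)**: two interleaved start states ("games",
  gold and silver), each with a left/right choice between fractals. A
  choice commonly (probability 0.70) leads to that action's majority
  second-stage state and rarely (0.30) to the alternative; each of the four
  second-stage states pays a coin (0.25 USD) with a probability that drifts
  across trials as an independent Gaussian random walk (increment SD 0.025,
  reflecting bounds 0.25/0.75). Choices cost 0.01 USD. Training lasts 200
  trials (100 per game, interleaved with no run longer than 4); then 4
  no-feedback trials (2 per game), the devaluation of one coin type
  (counterbalanced), a consumption display of 10 valued and 10 devalued
  coins, and 20 respond/withhold test trials (10 per game, randomized, no
  feedback).
* **Single-game variant (`"exp2"`)**: one game, 150 drifting trials
  followed by 50 trials with reward probabilities stabilized at 0.9 for the
  second-stage state associated with the to-be-devalued coin and 0.1 for
  the other; 4 no-feedback trials; devaluation; a 10-trial forced-choice
  habit test (withholding is not available and responding is free).

Reflection at a walk bound mirrors the proposal (`p -> 2*bound - p`,
repeated until inside). Walk initial values are uniform within the bounds,
and the interleaving and no-feedback allocations above are package
conventions where the design leaves them open; both are configurable.
Trial indices are 1-based everywhere, including exported CSVs, matching R
convention.

## The hybrid agent

Each simulated subject carries parameters `alpha` (learning rate), `beta`
(softmax inverse temperature), `w` (model-based weight), `pi`
(perseveration), a respond/withhold pair (`beta_resp`, `resp_bias`, used
only in the two-game variant's no-feedback/test phases), and an
eligibility parameter `lambda` (default 1).

The **model-free** system caches first-stage action values and
second-stage state values and updates both by a delta rule after observed
feedback:

    Q_mf(g, a) += alpha * ((1 - lambda) * V2(s) + lambda * r - Q_mf(g, a))
    V2(s)      += alpha * (r - V2(s))

With the default `lambda = 1` the terminal reward is credited directly to
the first-stage cache; this matches treating the previous-trial reward
main effect as the model-free signature in the regressions. The
**model-based** system evaluates actions prospectively through the known
transition structure,

    Q_mb(a) = p_common * u(dest_a) * V2(dest_a) + (1 - p_common) * u(alt_a) * V2(alt_a)

where `u(s)` is the current incentive value of the state's coin (1, or 0
after devaluation). Only this branch sees devaluation — that asymmetry is
the computational content of the devaluation test. The transition model is
fixed at the true 0.7/0.3 mapping (participants are instructed and trained
on the structure). Choice follows a softmax of
`beta * (w * Q_mb + (1 - w) * Q_mf)` plus a stickiness bonus `pi` on the
previous same-game choice. Values initialise at 0.5, the midpoint of the
reward-probability bounds, which avoids first-trial transients in either
direction.

During no-feedback and test trials nothing is learned (hidden feedback is
a contractual no-op) and no transition is played out; the devaluation
event changes `outcome_value` and nothing else. Both invariants are
enforced by tests.

### The respond/withhold mechanism

The two-game variant's test phase asks whether the subject engages at all.
The package models this with a logistic engagement rule on the net value
of playing:

    E = max_a [w * Q_mb(a) + (1 - w) * Q_mf(a)] * reward_value - response_cost
    P(respond) = logistic(beta_resp * E + resp_bias)

The model-based branch carries `outcome_value`, so devaluation zeroes it;
the cached model-free branch is untouched. This mechanism is a generative
convention of this package — the task motivates it conceptually (the value
of responding is the product of the coin's current value and the chance of
obtaining it) but does not prescribe a functional form.

**Defaults (`beta_resp = 60`, `resp_bias = -3.5`).** These were fixed once,
by calibration of the generator against the qualitative shape of the
observed behaviour: the engage/withhold threshold sits near `w = 0.5` and
the tails saturate, so a cohort with `w ~ U(0, 1)` produces the
characteristic bimodal devaluation-sensitivity histogram (peaks near 0 and
10), a `w = 1` sub-cohort means near 9.5 of 10, and a `w = 0` sub-cohort
mean within one response of 0. Under these defaults the rank correlation
between `w` and devaluation sensitivity in a 90-subject cohort is about
0.5–0.65; the irreducible noise comes from the 10-trials-per-state
binomial test and from fluctuation of the learned values at test time.

## Synthetic cohorts

`generate_cohort()` draws per-subject parameters from a `cohort_spec()`
(fixed value, uniform range, or arbitrary function per parameter) and
simulates every subject end-to-end. Defaults: `alpha ~ U(0.4, 0.7)`,
`beta ~ U(6, 10)`, `w ~ U(0, 1)`, `pi ~ U(0, 0.3)`. Learning rates in the
moderate range and decisive temperatures keep the learned values stable
enough that the lag-1 regression signatures are well estimated from 200
trials; the full-range `w` spans pure model-free to pure model-based
control. Consumption behaviour is a generator convention: each available
valued coin is collected with probability 0.55 and each devalued coin with
probability 0.06, making the manipulation check meaningful and matching
the scale of observed consumption differences.

A `deval_link = "null"` cohort severs devaluation from the agent's values:
engagement becomes a flat per-subject probability and choices ignore
outcome values. This provides the specificity control in which the
group-level slope should cover zero.

**What the generator does and does not emulate.** It reproduces the task
structure, reward statistics, phase schedule, devaluation and consumption
events, response lapses (as uniform random omissions at a configurable
rate), and parameter heterogeneity. It does not model reaction times,
drift-diffusion dynamics, forgetting, learned transition models, or any
between-system independence of model-free strength: every behavioural
consequence of devaluation flows through the single weight `w`. Passing
tests therefore demonstrate internal consistency of the method chain on
cohorts whose habit/goal-directed balance is one-dimensional — they do not
show that human cohorts satisfy that restriction. One visible consequence,
established during calibration and worth stating plainly: because the
model-free choice weight is `(1 - w) * beta`, the per-subject model-free
index is itself a strong negative correlate of `w` in synthetic cohorts,
which makes the two indices collinear proxies of the same quantity. The
sign structure of the index analysis (model-based positive, model-free
near zero) reproduces, but the model-based partial effect does not reach
significance in as large a fraction of replicate cohorts as it did in the
human sample, where model-free strength evidently varied independently.

## Stay-probability analyses

`build_lagged_design()` lags within game: the predictors of a choice are
the reward (+1/-1) and transition type (+1/-1) of the previous trial
experienced in the same game, and `stay` is defined relative to the
previous same-game choice. Missed trials are excluded as targets and as
lag sources; the first usable trial per game emits no row; the stabilized
tail of the single-game variant is excluded by default because only the
drifting trials assess trial-by-trial learning.

`fit_mixed_stay_model()` fits
`stay ~ reward * transition * deval_z + (1 + reward * transition | subject)`.
Two engines are provided. The `"glmer"` engine is the reference: lme4's
Laplace-approximated mixed logistic model with full random-effect
covariance — the canonical engine for exactly this model class. The
`"twostage"` engine is the fast approximation used in continuous testing:
per-subject Firth-penalized logistic fits of `stay ~ reward * transition`,
followed by a DerSimonian–Laird random-effects meta-regression
(`metafor::rma`) of each within-subject coefficient on the standardized
devaluation score; intercepts give the within-subject terms, slopes the
devaluation interactions. Firth's Jeffreys-prior penalty keeps per-subject
estimates finite under perfect stay/switch patterns (separation), which
occur regularly in strongly perseverative or decisive subjects.

`per_subject_indices()` extracts the model-free index (reward beta) and
model-based index (reward-by-transition beta) from the basic model without
the between-subject predictor, either as subject-level effects of the
hierarchical fit (default; empirical-Bayes shrinkage borrows strength
across subjects) or as independent Firth fits (flagged variant).
`predict_devaluation()` is the ordinary linear model of devaluation
sensitivity on the standardized indices, with optional covariates
(consumption sensitivity, comprehension fail count) and their interactions
with the model-based index.

P-values: Wald z for `glmer` and for the meta-regression; the hierarchical
RL fit below reports doubled posterior sign probabilities, labelled as
such.

## Likelihood and estimation

`hybrid_nll()` scores observed first-stage choices under the same compiled
update kernel the simulator uses (one C++ implementation serves both, so
the likelihood replays internal state exactly as the generator produced
it). Hidden-feedback trials contribute choice likelihood but no updates;
missed trials contribute nothing; post-devaluation test choices are
excluded by default. The test suite pins the kernel against an
independently written brute-force oracle to 1e-10 and against the exact
flat-policy value `T * ln 2`.

`fit_mle()` minimizes the likelihood on unconstrained scales (logit for
`alpha` and `w`, log for `beta`) by Nelder–Mead with 10 random restarts.
`recover_parameters()` is the validation harness: simulate with known
parameters, refit, report rank correlations, bias and RMSE. At the default
cohort and 200 trials per subject, `w` recovers with Spearman correlation
about 0.9, and recovery sharpens with longer training, as consistency
requires. With `beta = 0` the likelihood is flat in `w` and the report
flags the cohort rather than returning spurious precision.

`fit_hierarchical()` is the package's own MCMC sampler for the
hierarchical model: transformed subject parameters drawn from independent
group Gaussians, with the group mean of logit-`w` a linear function
`a + b * deval_z` of each subject's standardized devaluation sensitivity.
Priors are weakly informative: Normal(0, 1.5^2) on group means and the
slope, half-Normal(0, 1) on group SDs; the devaluation covariate enters
only `w`'s group mean by default, with a flagged all-parameter variant for
the specificity analysis. The sampler is Metropolis-within-Gibbs:
per-subject random-walk updates one parameter dimension at a time,
vectorized across subjects through a single compiled cohort-likelihood
call; conjugate Gibbs draws for means and the slope; log-scale random-walk
updates for the SDs. Proposal scales adapt only during warmup (target
acceptance 0.44). Split-Rhat and a Geyer-truncated effective sample size
are computed for every group quantity, and any Rhat above 1.1 flags the
result with a warning status — the result is still returned, with
diagnostics, never silently. Chains are initialised from quick per-subject
maximum-likelihood fits, jittered per chain.

Sampler sizes: the full profile runs 4 chains of 1500 warmup + 1500 kept
draws; the reduced profile used in continuous testing runs 2 chains of
600 + 600. A random-walk sampler needs more sweeps than a gradient-based
one for the same effective sample size, and the compiled likelihood makes
sweeps cheap, so the sizes were set to where the slope `b` and the group
means mix well (Rhat near 1, ESS in the hundreds). Residual slow mixing is
confined to the perseveration group-SD (a centred-hierarchy funnel when
that SD is small) and is reported honestly by the diagnostics rather than
masked.

## Quality control and metrics

Devaluation sensitivity is the count difference (valued minus devalued
responses, -10..10) in the two-game variant and the proportion of valued
choices in the single-game variant. Consumption sensitivity is the
valued-minus-devalued collected-coin difference. Exclusions follow three
strict rules: more than 10% of training trials missed, the same key on
more than 90% of responses, or a mean reaction time beyond 2 SDs of the
cohort mean (applied to per-subject means when an RT summary is supplied;
simulated logs carry no RTs). The filters are idempotent — RT bounds are
frozen from the first application. Spearman correlations use average ranks
for ties.

## Numerical choices and degenerate inputs

Logit differences in the softmax are clipped at +/-35 before
exponentiation; likelihood probabilities are floored at 1e-300; `beta` is
capped at 1e3 inside the optimizer to keep the kernel finite under extreme
proposals. Firth fits damp Newton steps larger than 5 and report
non-convergence. Z-scoring a constant vector, empty trial sets, cohorts of
fewer than 2 subjects (10 for the hierarchical fit), consumption counts
outside 0..10, and configurations with inverted walk bounds are all
rejected with explicit errors. Reproducibility is by explicit seeds
everywhere; a master seed expands into per-stage child seeds by a fixed
counter scheme (`child_seed()`), so any pipeline stage can be rerun in
isolation.

## Problem sizes

The analyses in `analysis/` and the acceptance script use cohorts of 90
subjects with 200 training trials (the study conditions), 30-subject
cohorts for the reduced-profile hierarchical fits, 100-subject recovery
runs at 200 and 2000 trials, and Monte-Carlo checks of the generator at
1e5 steps. These sizes were chosen to estimate each quantity to the
precision its check requires.

## Known limitations

* Devaluation behaviour is one-dimensional in `w` by construction; see the
  cohort section for what that implies about the index analysis.
* The respond/withhold rule is a package convention, not an empirical
  claim; its parameters shape the mapping from `w` to test behaviour.
* The hierarchical sampler assumes independent group dimensions
  (diagonal covariance across parameters); subject-level posteriors within
  a parameter are exact up to MCMC error, but cross-parameter group
  correlations are not modelled.
* No reaction-time model: the RT exclusion rule activates only when an
  external RT summary is supplied.
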