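---
title: "Modelling probabilistic reversal learning: task, models, and hierarchical fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling probabilistic reversal learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revlearn)
```

This vignette is the package's account of its science: the generative
task model, the Q-learning family, the hierarchical estimation
machinery, and the numerical and design choices behind them. It states
no empirical result that the test suite and `scripts/acceptance.R` do
not themselves compute.

## The task as a generative model

A session is a sequence of `n_trials` (default 200) binary choices
between symbols A and B. One symbol is *good*: choosing it wins with
probability `p_reward_good` (default 0.8); the other symbol's outcome
probabilities are the complement, so the two options are perfectly
dependent. The reversal machinery is a two-state hazard process:

* **Arming.** After each trial, the criterion is re-evaluated over the
  sliding window of the last `criterion_window` (6) *answered* trials;
  at least `criterion_hits` (5) correct choices arm the hazard. The
  window must be full — the criterion is not evaluable before six
  answered trials exist, so early trials never arm it. This resolves
  what a partial window should mean by never asking the question.
* **Firing.** Entering a trial armed, the contingency reverses with
  probability `reversal_hazard` (0.2) before the choice. A fired
  reversal disarms the state; otherwise the state simply tracks the
  window, so losing the criterion also disarms it.

Feedback is ±10 SEK; the session payout is the clamped sum (30–300
SEK). Timing uses a 1.5 s stimulus window, 1 s feedback, and an
inter-trial interval drawn by inverse-CDF sampling from an exponential
(rate 1.0 s⁻¹, exposed as `iti_rate`) truncated to `iti_range`. Task
descriptions of this paradigm give the ITI bounds inconsistently (1 or
1.5 s lower bound); the package adopts 1.5–6.5 s and leaves both the
bounds and the (rarely reported) rate configurable. Onsets accumulate
from session start: stimulus, feedback at stimulus + 1.5 s, then
feedback duration plus ITI.

Missed trials (simulated with `miss_probability`, default 0) produce no
outcome, no value update, and do not enter the criterion window: a
non-response is treated as outside the learning process, not as an
incorrect choice. Left/right screen position is presentation-level
randomization with no role in the generative model, and is therefore
not modelled at all.

## The model family

All variants are Rescorla–Wagner learners over the two Q-values with a
unit-temperature softmax choice rule. The experienced reinforcement is
`beta_rew` on a win and `beta_pun` on a loss, so the sensitivities
absorb what would otherwise be an inverse temperature — a free
temperature would be exactly confounded with the scale of the
sensitivities, so it is fixed at 1 and the sensitivities are left on
their natural scale (group means near +2 and −1 in healthy adults on
this task). `beta_pun` is not sign-constrained; only the prior
initialization (−1) encodes its typical sign.

The factorial family crosses three binary choices:

* **Double vs single update.** Double-update variants move the
  unchosen option toward the *opposite* reinforcement, `−R`, with the
  same learning rate, exploiting the dependent contingencies. An
  algebraic consequence — used as a correctness oracle in the tests —
  is that each answered trial contracts the sum `Q(A) + Q(B)` by
  `(1 − alpha)`, so the sum decays geometrically to zero from its
  initial value `q_init`. (A variant updating the unchosen option
  toward the opposite *sensitivity* would instead drive the sum to
  `beta_rew + beta_pun`; that is a different model, not implemented.)
* **Separate vs common sensitivities.** Common-sensitivity variants
  constrain `beta_pun = −beta_rew`.
* **Free vs fixed initial value.** `q_init` is the starting Q-value of
  the option recorded as A in the session file (option B starts at 0),
  a bias to initially prefer one stimulus. Fixed variants pin it at 0.

Missed trials contribute no likelihood term and freeze the Q-values,
mirroring the simulator. Restricted variants are exact submanifolds of
the full model: at `beta_pun = −beta_rew` and `q_init = 0` the
likelihoods coincide identically, which the tests assert.

## Hierarchical estimation

Inference runs in an unconstrained space: `a = logit(alpha)`, with the
sensitivities and `q_init` mapped by identity. The group-level prior is
a diagonal Gaussian over the active coordinates; diagonality keeps the
moment-matching M-step closed-form and matches how such empirical-Bayes
fitters are conventionally built.

**E-step.** Each session is fitted by MAP under the current prior using
BFGS from multiple starts — the prior mean plus draws from the prior
(5 starts in the first iteration; later iterations warm-start from the
previous optimum). An optimizer result is never accepted if it is worse
than its own starting point, and ties break by first occurrence. The
subject-level posterior is Laplace-approximated at the optimum: the
covariance is the inverse Hessian of the negative log posterior,
computed by central finite differences with step `1e-4` (the likelihood
is smooth; hand-coded second derivatives buy nothing), and the log
evidence is `loglik + log prior + (d/2) log 2π + ½ log det Σ`. A
non-positive-definite Hessian is ridged (escalating diagonal loading)
and flagged.

**M-step.** The prior mean is the average MAP; the prior variance is
the average of squared MAPs plus Laplace variances minus the squared
mean, floored at `1e-6` to prevent collapse when sessions are nearly
identical.

**Convergence and monotonicity.** The objective is the summed Laplace
log evidence. Exact EM increases the true marginal likelihood
monotonically, but the MAP-plus-Laplace approximation can wiggle by a
small amount at the optimum. `run_em` therefore keeps the best iterate:
iteration stops when the objective improves by less than `tol`
(default 0.02 nats across the cohort), and an iteration that would
*decrease* the objective is rolled back, so the reported trace is
non-decreasing by construction and the returned fit is always the best
one visited. Both crossover sessions of a subject enter one pooled
group prior and receive separate parameters; pooling is the natural
choice when the group prior is a regularizer rather than an object of
inference, and a per-condition prior would leak the condition label
into the estimates being compared across conditions.

**Degenerate inputs.** A session with no answered trials is rejected; a
single-trial session is fitted, with the prior dominating every weakly
identified dimension (tested). EM requires at least two sessions and
aborts with the trace attached if the objective turns non-finite.

## Model selection

Session-wise Laplace log evidences — not raw likelihoods — feed the
random-effects group selection, since the evidence carries the
parameter-count correction that raw likelihood lacks. The variational
Dirichlet scheme iterates responsibilities and counts to `Δα < 1e-6`
with a uniform prior `alpha0 = 1`; exceedance probabilities are
Monte-Carlo estimates from `1e5` Dirichlet draws (sampling error about
±0.003 at probabilities near 0.5, immaterial near 0 or 1). The pooled
winner is reported together with per-session-label selections and a
consistency flag, reflecting the design requirement that a winning
model should win in both conditions. `ibic` provides the fixed-effects
companion: −2× summed evidence plus `2d · log(total answered trials)`,
penalizing the 2·d group hyperparameters.

## Behavioral battery

Percent correct, switches and reversal counts are computed over
answered trials only. Paired comparisons use the classic paired t with
the paired-design effect size `d = t/√n` — the convention under which a
t of −2.448 at n = 29 corresponds to d = −0.455. Reversal counts use
the Wilcoxon signed rank with zeros dropped, mid-ranks for ties, and a
tie-corrected normal approximation without continuity correction,
reported as a z value; an exact sign-permutation oracle in the tests
bounds the approximation error at small n. The exploratory
feedback-sensitivity analysis computes, per session, the probability of
switching stimulus after a win and after a loss (consecutive answered
trials only; missed trials break the chain), takes per-subject
session-contrast deltas, and contrasts delta-after-loss against
delta-after-win with a paired t. Subjects lacking a cell are dropped
from the contrast and logged. Exclusion follows the task's convention:
a subject is removed entirely if any session reached fewer than 5
reversals.

## What the synthetic cohort does and does not emulate

`generate_cohort` draws session-level parameters from a group Gaussian
in inference space — means `(a, b_rew, b_pun, q0) = (−0.85, 2.0, −1.0,
0)` (a learning rate near 0.30) and SDs `(0.8, 0.87, 0.5, 0.3)` — and
plays each through the full task. The sensitivity means and their
spread match the scale reported for healthy volunteers on this task;
the learning-rate mean and the SDs are chosen once as representative of
individual variation in such cohorts. Two sessions per subject are
drawn independently from the same population: the generator encodes
*no* drug effect and no within-subject parameter correlation. Passing
recovery and calibration tests on this cohort therefore shows that the
machinery is unbiased and well-calibrated under the null at the study's
size — it does not validate the model against real choice sequences,
response times, practice effects, session-order effects, or the
within-subject dependence real crossover data would show.

Type-I calibration of the punishment-sensitivity comparison is checked
on 1000 replicate null cohorts drawn at the parameter level (paired
t on per-session draws from the same population): the calibration of
the test statistic is a property of the statistics module, and
hierarchical refits of 1000 cohorts would add computation without
adding information about it.

## Problem sizes and runtimes

The test suite uses cohorts of 6–12 subjects for EM properties, the
full 30-subject × 2-session × 200-trial scale for parameter recovery,
20 subjects per generator condition for the 8×8 model-recovery matrix,
100,000 pooled trials for the contingency audits, and 1000 replicates
for calibration — sizes at which every Monte-Carlo check has comfortable
margins while the whole suite completes in minutes on a single core.
The acceptance script pools 100,000 trials (contingency) and 2,000
sessions (hazard).

## Known limitations

* The Laplace evidence is a local Gaussian approximation; with few
  answered trials or boundary-flat likelihoods it can misstate the
  complexity penalty. The multi-start E-step mitigates, but does not
  eliminate, multimodality.
* The group prior is diagonal; correlated individual differences
  (e.g., between the two sensitivities) are absorbed into the
  per-session fits rather than the prior.
* No response-time model: simulated sessions carry onsets but no RTs,
  so RT comparisons run only on real-format data that includes them.
* Exceedance probabilities are unprotected (no null-of-equal-models
  correction) and family-level inference is not implemented.
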