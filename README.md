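# revlearn

Computational-behavior analysis of probabilistic reversal learning in
within-subject pharmacological crossover designs. The package is for
researchers who need the full modelling pipeline around such a task when
raw behavioral data cannot be redistributed: a generative simulator of
the task and of the learning agents, hierarchical model fitting, group
model selection, the model-free behavioral battery, and export of
trial-by-trial prediction errors for neuroimaging first-level models.

## The task and the model

Participants choose repeatedly between two symbols. The currently *good*
symbol yields a win (+10 SEK) with probability 0.8 and a loss (−10 SEK)
otherwise; the contingencies of the two symbols are dependent (the other
symbol wins with probability 0.2). Once the learning criterion — 5
correct choices among the last 6 trials — is met, the contingency
reverses with probability 0.2 on each subsequent trial until it does, or
until the criterion is lost. A session has 200 trials; the summed
winnings are clamped to 30–300 SEK.

Choice behavior is modelled by a family of eight Rescorla–Wagner
Q-learning variants. With Q-values *Q*(*a*), *Q*(*b*) and a chosen
option *c* receiving outcome-dependent reinforcement

&nbsp;&nbsp;&nbsp;&nbsp;*R* = *β*<sub>rew</sub> (win) or *β*<sub>pun</sub> (loss),

the trial-wise prediction error is *δ* = *R* − *Q*(*c*), the chosen
option updates as *Q*(*c*) ← *Q*(*c*) + *α δ*, and — in double-update
variants, which exploit the dependent contingencies — the unchosen
option *u* updates toward the opposite reinforcement,
*Q*(*u*) ← *Q*(*u*) + *α*(−*R* − *Q*(*u*)). Choices follow a
unit-temperature softmax of the Q-difference; the sensitivities carry
the reinforcement magnitude. The 2×2×2 family crosses double vs single
update, separate vs common win/loss sensitivities, and a free vs fixed
initial Q-value bias; `"DU-SS-Qi"` is the full model.

Parameters are estimated per session by hierarchical
expectation-maximization: MAP estimation under a group-level Gaussian
prior in an unconstrained space (logit learning rate), with a Laplace
approximation supplying per-session covariances and log model
evidences; the group moments are re-estimated each iteration. Models
are compared by random-effects Bayesian model selection (Dirichlet
posterior over model frequencies, exceedance probabilities), with an
integrated-BIC fixed-effects companion criterion.

## Worked example

Simulate a 30-subject, two-session crossover cohort of double-update
agents, fit the winning model, and run the behavioral battery:

```r
library(revlearn)
cohort <- generate_cohort(n_subjects = 30, seed = 1)
fit <- run_em(model_spec(), cohort$sessions, seed = 1)
print(fit)
#> Hierarchical EM fit of model DU-SS-Qi: 60 sessions, 25 iterations (converged)
#>   final objective (sum log evidence): -5109.287
#>   group prior mean: a=-0.844, b_rew=2.110, b_pun=-1.176, q0=-0.184
```

The recovered group means sit close to the generating population
(learning-rate logit −0.85, reward sensitivity 2.0, punishment
sensitivity −1.0). Both sessions were generated from the same
population, so the crossover comparisons are null, and the battery
reports them as such:

```r
kept <- apply_exclusion(cohort)$kept
bat <- behavior_battery(kept, estimates = fit$estimates)
subset(bat$tests, measure %in% c("beta_rew", "beta_pun", "n_reversals"))
#>       measure                 test statistic df p_value effect_size
#> 3 n_reversals wilcoxon_signed_rank   -0.0799 NA   0.936          NA
#> 4    beta_rew             paired_t   -0.1834 29   0.856     -0.0335
#> 5    beta_pun             paired_t   -0.4556 29   0.652     -0.0832
```

`statistic` is the paired t (or Wilcoxon z) for the ghrelin-minus-
placebo contrast and `effect_size` the paired Cohen's d = t/√n.
Prediction errors under the fitted parameters export as
parametric-modulator event tables, one `feedback` row per answered
trial (mean-centered modulator) and a `no_response` row per missed
trial:

```r
ev <- export_pe_events(cohort$sessions[[1]], fit$spec,
                       fit$subject_fits[[1]]$params)
head(ev, 3)
#>   onset duration trial_type modulator trial
#> 1  1.50        1   feedback     2.188     1
#> 2  5.54        1   feedback     1.761     2
#> 3  9.78        1   feedback    -0.367     3
```

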