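---
title: "Methods: the hideseek task, observer and decision models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the hideseek task, observer and decision models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the modelling assumptions behind **hideseek**:
the generative task, the reduced-Bayesian observer, the behavioural
coding rules, the mixed-effects decision models, and the synthetic-child
generator used to validate the whole chain. It also records the design
choices that were genuinely open and why they were resolved the way
they were.

## 1. The task model

Each of three characters hides at 1-D locations on a hedge normalized
to $[0,1]$ (0 = far-left corner). Character $c$'s location on trial $t$
is drawn from $\mathcal N(\mu_{c,t}, \sigma_c^2)$ truncated to the
hedge; with per-trial hazard $H_c$ the mean $\mu_{c,t}$ is redrawn
uniformly on $[0.1, 0.9]$ (a changepoint). $\sigma_c$ is the *noise*
level, $H_c$ the *volatility*.

**Defaults.** The task description orders the characters qualitatively
(high noise/low volatility, low noise/high volatility, intermediate)
without printing numbers, so the defaults are a design choice:
$\sigma \in \{0.12, 0.04, 0.08\}$ screen widths and
$H \in \{0.04, 0.25, 0.12\}$. They preserve the ordering while keeping
each pattern learnable within a ~35-trial session; all are
configurable, and an explicit `mean_schedule` can replace the hazard
process when hand-crafted schedules are wanted.

**Numerical choices.** New means keep a 0.1 margin from the edges so
the Gaussian mass is mostly on-screen; truncation is by rejection
sampling, not clipping, because clipping creates point masses at 0/1
that bias prediction errors. A pattern's clock advances only on trials
played with that character. `noise_sd = 0` is allowed as a degenerate
testing configuration (the sampler then returns the latent mean).

## 2. The reduced-Bayesian observer

The observer is the two-hypothesis (changepoint vs continuation)
approximation to full Bayesian changepoint inference. Per character it
carries a belief $B$, a relative uncertainty
$\tau = \sigma_B^2 / (\sigma_B^2 + \sigma_n^2)$, and a noise estimate
$\sigma_n$. For each (prediction, outcome) pair:

1. $\delta = \text{outcome} - \text{prediction}$, $PE = |\delta|$,
   $LP = PE_{t-1} - PE_t$ (missing on a character's first trial).
2. $\Omega = \dfrac{H\,U}{H\,U + (1-H)\,\varphi(\delta;\,0,\,\sigma_n^2/(1-\tau))}$,
   with $U = 1$ the uniform density over the hedge and $H$ the
   observer's *subjective* hazard (children are not told the true
   volatilities, so a single $H = 0.1$ is used for all characters).
3. $\alpha = \Omega + (1-\Omega)\tau$ and $B' = B + \alpha\delta$
   (projected into $[0,1]$).
4. $\tau$ is propagated through the $\Omega$-weighted mixture of the
   changepoint branch (variance resets to the value implied by
   `tau_reset`) and the continuation branch (conjugate shrinkage
   $\tau \to \tau/(1+\tau)$), plus the between-branch mean spread
   $\Omega(1-\Omega)\,(\delta(1-\tau))^2$. With the default
   `tau_reset = 0.5` the reset equals the conjugate value after a
   single observation under a flat prior, and $\Omega = 1$ gives
   exactly $\tau' = 0.5$.
5. Expected PE is the folded-normal mean of the predictive
   distribution, $\sqrt{2/\pi}\,\sigma_n/\sqrt{1-\tau}$; expected LP is
   an exponentially smoothed recent PE (decay $\lambda = 0.5$, a
   two-to-three-trial memory) minus expected PE — zero at convergence,
   positive while errors are still expected to shrink.
6. Novelty is the population-SD z-score of the negated pick counts
   across the three characters; equal counts give all zeros.

$\tau$ is initialised from a uniform prior over the hedge,
$\tau_0 = (1/12) / (1/12 + \sigma_n^2)$, and $B_0 = 0.5$.

**Online noise estimation (default).** Each character's $\sigma_n^2$ is
tracked by an exponentially weighted estimate of
$\delta^2(1-\tau)$ — whose expectation is $\sigma_n^2$ under
continuation — with learning rate `noise_lr * (1 - Omega)` (default
0.2, gated so changepoints do not masquerade as noise) and clamped to
$[10^{-4}, 0.09]$. The alternative `noise_est = "fixed"` holds
$\sigma_n$ at its initial value (default 0.08). The online default was
chosen because with a common fixed $\sigma_n$ the expected-PE covariate
is nearly constant across characters, which makes expected LP almost an
affine function of recent PE; the expectation-based and history-based
choice models then become nearly indistinguishable by construction.
Tracking each character's noise restores the conceptual distinction:
expected PE absorbs the character's irreducible error level, and
expected LP isolates the *reducible* part. The fixed mode is retained
(and used where a test oracle requires a known noise level).

**Model-filtered vs raw covariates.** Regression covariates use the
observer's quantities computed from the logged predictions themselves
(PE is the raw unsigned error; $\Omega$, $\alpha$, expected PE/LP are
model-filtered). The observer state persists across switches: leaving a
character does not erase memory of it.

**Approximation quality.** The package's tests compare $\Omega$ with an
independently coded two-hypothesis Bayes computation (agreement to
$10^{-10}$) and the $\tau$ trajectory with a full Bayesian run-length
filter on 200-trial sequences at hazard 0.15 (mean absolute difference
well under 0.1). The approximation degrades gracefully as hazard grows;
at hazard 0.25 the discrepancy approaches 0.1.

## 3. Behavioural coding

A trial is a **leave** when the next trial is played with a different
character; the label sits on the trial *preceding* the switch, so every
predictor in the leave–stay model is computable from information
available at the decision point. The final trial of a session is
censored (`NA`), not coerced to "stay". Each leave yields a **choice
event** recording the chosen character and the unique unchosen
alternative; switches to a never-visited character are flagged and
excluded from choice modelling (expectations are undefined there), as
are events whose alternative was never visited. The inclusion rule —
at least 10 trials with every character — is a configurable threshold.
The `time` covariate is the session-level trial index (the logs carry
an optional `timestamp_s` column, but elapsed time is not modelled).

## 4. Decision models

All mixed models use lme4 with participant random intercepts and
Laplace estimation (`nAGQ = 0` is available for Monte-Carlo loops);
inference is Wald $z$, matching the reported statistics of studies in
this paradigm. Continuous predictors are z-scored across the analysis
sample so coefficients and odds ratios are per-SD; recovery experiments
instead divide by the fixed reference scales in
`hs_reference_scales()`, so fitted coefficients live on the generator's
scale.

- **Performance.** `pe ~ within_character_trial` with by-participant
  random slopes; each child's performance score is the fixed slope plus
  the empirical-Bayes deviation (negative = learning). If the mixed fit
  fails, per-child least-squares slopes are substituted and flagged.
- **Leave–stay.** `leave ~ pe + lp + novelty + time + performance +
  performance:(pe + lp + novelty) + (1 | participant)`. Performance's
  main effect is included by default (`include_performance_main =
  FALSE` drops it, since the source analyses list only the
  interactions and time). Rows with undefined LP (each character's
  first trial) are removed listwise and counted in the returned object.
  Marginal effects of novelty and LP at ±1 SD of performance use
  delta-method CIs; VIFs are computed from the fixed-effects design
  matrix as $1/(1-R_j^2)$.
- **Exploratory choice.** Within each event the two options are put in
  a random (seeded) order; the response is "chose option 1" and every
  predictor is an option difference. This framing was chosen because
  the response coding is not dictated by the data; a symmetry test
  verifies the fit is invariant (up to sign) to relabelling. The
  expectation model uses ΔexpLP and ΔexpPE; the history variant
  replaces them with the last experienced ΔLP and ΔPE. Both variants
  are fitted to the identical event rows (listwise deletion on the
  union of predictors) so AIC/BIC comparison is well defined.

## 5. The synthetic-child generator

Agents carry the same observer the analysis uses and update it on their
own *emitted* (motor-noisy) predictions, exactly as the analysis
recomputes covariates from the logged data — so when the agent's
learner parameters match the analysis defaults, the generating
covariates and the analysis covariates agree exactly, and the fitted
models are correctly specified under the generator. That is a
deliberate best case: passing calibration and recovery shows the
estimation machinery works, not that the model family is right for
real children.

- **Stay–leave policy:** logistic in the analysis covariates with
  coefficients on reference scales; defaults put novelty and LP effects
  in interaction with latent performance (0.73 and 0.49, the fitted
  magnitudes of the study this task reproduces), intercept −1.1
  (≈25% leave rate) plus a per-agent N(0, 0.3) intercept deviation.
- **Choice policy:** softmax over the two options' values
  $\theta_{expLP}\,expLP + \theta_{expPE}\,expPE + \theta_{nov}\,nov$,
  defaults (0.35, −0.21, 0.30) — all three fitted magnitudes, including
  the non-significant expected-PE avoidance, because the generator's
  job is to emulate the observed behaviour and the point estimates are
  its best description.
- **Heterogeneity:** each agent draws a latent score $p \sim N(0,1)$
  (higher = worse); its learning rate is multiplied by
  $\min(1, e^{-0.7p})$ and its motor noise (default SD 0.06 screen
  widths) inflated by $1 + 0.35\max(0,p)$, producing a continuum of PE
  slopes from clear learning to none. Setting `heterogeneity = 0`
  yields homogeneous normative agents; recovery experiments default to
  this best case and can feed the generating latent performance to the
  fits, isolating coefficient recovery from slope-estimation error.
- **Session length:** sessions end by a per-trial quit probability
  (0.05, active from trial 10) or once any character reaches 35 trials.
  The quit probability was calibrated once so the default mean session
  length is ~28 trials, matching the observed mean; only the mean was
  targeted, since the full length distribution is not available.
  Fixed-length sessions (`n_trials_fixed`) replace the quit rules in
  calibration designs.

What the generator does **not** emulate: attention and fatigue
dynamics, prompting by an experimenter, 2-D screen geometry, response
times, and any dependence of quitting on learning. Consequently, a
pipeline that is well calibrated here can still be biased on real data
if those features matter.

A note on inclusion: with a ~28-trial mean session, requiring ≥10
trials with each of three characters excludes most simulated children
(the rule needs ≥30 trials plus even coverage). The observed study
reports both the ~28-trial mean and a much higher inclusion fraction,
which cannot both hold under this reading of the rule; the simulator
reproduces the session-length statistics and accepts the low inclusion
rate, and the threshold is configurable.

## 6. Monte-Carlo problem sizes

The validation suite uses: 1,000 random inputs for the $\Omega$ oracle;
five 200-trial sequences for the run-length-filter comparison; 500
replicates of 20 children × 30 trials for null calibration (pooled Wald
rejection at $\alpha = .05$ expected in $[0.03, 0.08]$); 100 replicates
of 100 children × 40 trials for choice-coefficient recovery (2-SE
coverage ≥ 90%); and 100 cohorts of 87 children × 40 trials for the
expectation-vs-history model-selection check (AIC preference ≥ 80%).
These sizes keep each study's Monte-Carlo error comfortably below the
margins being asserted. Mixed-model fits inside the large loops use
`nAGQ = 0`; all reported single-cohort analyses use the Laplace
default.

## 7. Known limitations

- The observer is a reconstruction of the reduced-Bayesian family from
  its published structure, with every constant exposed in
  `learner_config()`; it is not a bit-level replica of any particular
  implementation, and its expected-PE/expected-LP definitions are one
  reasonable instantiation among several.
- Wald inference in small samples (few events per child) can be
  mildly anticonservative; the null-calibration study bounds this
  under the generator, not under arbitrary real-data conditions.
- Per-child performance slopes are weakly identified when
  within-character runs are short; empirical-Bayes shrinkage then
  compresses the slope distribution, attenuating performance
  interactions relative to their latent generating values.
- The full Bayesian run-length filter is used only as a test oracle;
  the production path is always the reduced observer.
- Learner hyperparameters are fixed per analysis, not estimated per
  child by maximum likelihood.
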