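---
title: "The flexible control model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The flexible control model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexcontrol)
```

## The problem and the model

In conflict tasks such as the Stroop paradigm, responses are slower when a
task-irrelevant feature conflicts with the required response (incongruent
trials). People adapt: when incongruent trials are frequent, the conflict
cost shrinks, consistent with attention being allocated in proportion to the
*predicted* conflict level. When the conflict rate itself changes over time,
an adaptive learner must additionally estimate the *volatility* of the
environment and translate it into a learning rate: high in changeable
stretches (trust recent trials), low in stable stretches (integrate long
histories).

`flexcontrol` implements this idea as a hierarchical Bayesian filter over a
discrete grid of two latent variables:

* `f` — predicted conflict level, the believed probability that the next
  trial is incongruent;
* `alpha` — the flexible learning rate, a belief about the rate of change of
  the conflict level. We use "volatility belief" and "flexible LR"
  interchangeably.

Per trial, in order:

1. **LR transition.** `alpha` stays put with probability `k_stay`, otherwise
   jumps to a uniformly drawn node. This jump-to-uniform transition needs no
   prior knowledge of when or how often the environment changes.
2. **Conflict propagation.** Conditional on `alpha`, the belief over `f`
   diffuses through a beta kernel with *mode* at the current `f` and
   parameter sum `s(alpha)`, strictly decreasing in `alpha` — a stronger
   volatility belief yields a wider next-trial conflict distribution. The
   pre-stimulus posterior means of `alpha` and `f`, and the s.d. of the `f`
   marginal (the *estimation uncertainty*), are recorded at this point: they
   are the model's trial-wise predictions, made before the stimulus is seen.
3. **Congruency update.** The observed congruency `o` multiplies the belief
   by `f^o (1-f)^(1-o)`.
4. **Reaction-speed update.** Reaction speed `RS = 1/RT` is modelled with
   congruency-specific Gaussian emissions `RS ~ N(a_c + b_c f, sigma_c)`;
   observing RS therefore also informs the latent state. Error trials carry
   no RT; they contribute only the congruency update.

Runs are concatenated without belief reset: each run's 16-trial, 50%
burn-in block performs the resetting role that the task design intends.

The posterior-mean dynamics have the form of a Rescorla–Wagner rule
`f <- f + lr_eff * (o - f)` with a state-dependent effective learning rate.
The sign of every prediction change matches the sign of the prediction
error (this is exact for the congruency-only filter and is enforced by a
property test). Quantitatively, the effective rate is an attenuated,
nonlinear function of the posterior-mean `alpha` — see "Known limitations".

## Tunable parameters

| Parameter | Default | Units / range | Role |
|---|---|---|---|
| `n_alpha`, `n_f` | 50 × 50 | nodes | grid resolution (midpoints of (0,1)) |
| `k_stay` | 0.993 | probability | LR transition stickiness |
| `s(alpha)` | `2 + 4/alpha^3` | — | beta kernel parameter sum |
| `a_con`, `a_inc` | 2.6, 2.0 | 1/s | RS intercepts |
| `b_con`, `b_inc` | −0.4, +0.4 | 1/s | RS slopes on `f` |
| `sigma_con`, `sigma_inc` | 0.25 | 1/s | RS noise s.d. |
| `error_rate` | 0.058 | probability | generator error injection |
| `outlier_rate`, `outlier_scale` | 0.01, 3 | — | generator RT-outlier injection |
| LR search grid | 0.01–0.5 by 0.001 | — | fixed-LR exhaustive search |
| `mc_samples` | 1e5 | draws | exceedance Monte Carlo |

**Calibrating `s(alpha)` and `k_stay`.** The discretization, the exact
`s(alpha)` mapping and `k_stay` are implementation choices: the model family
only requires `s` to decrease in `alpha`. We calibrated both against the
phenomena the model family is meant to exhibit, using only the simulator
(never the acceptance outcomes of any external data): (i) on a stationary
80%-incongruent stream the long-run predicted conflict should approach 0.8;
(ii) in the volatility-manipulated design the fitted LR should be reliably
higher in volatile than in stable runs for essentially every subject, and
should rise within a few trials of a proportion-congruency switch. These
pull in opposite directions: (i) needs nodes whose conflict tracker
integrates hundreds of trials (large `s`) and enough transition stickiness
for the posterior to settle on them, while (ii) needs mass to move between
fast and slow nodes within a block. The cubic map `s = 2 + 4/alpha^3` with
`k_stay = 0.993` gives the best joint behaviour we found: about a quarter of
the 50 nodes hold slow, precise trackers (`s > 300`), the upper half reacts
within a few trials, long-run tracking of a 0.8 stream reaches ≈ 0.76, and
the volatile-over-stable LR separation holds in every simulated subject.
Steeper stickiness (≥ 0.995) improves tracking slightly but makes the
volatility signature unreliable; shallower maps (`s = 2 + g/alpha` or
`g/alpha^2`) track noticeably worse.

**Emission defaults.** The generator's defaults encode the two behavioural
facts the analysis is meant to recover: responses are slower on incongruent
trials, and slower the larger the control prediction error `|o − f|`. With
`RS_con = 2.6 − 0.4 f` and `RS_inc = 2.0 + 0.4 f`, reaction times at
`f = 0.5` are ≈ 417 ms (congruent) and ≈ 455 ms (incongruent), and RS
declines by 0.4 per unit of `|o − f|` in both conditions. (A superficially
natural alternative — equal-magnitude intercepts around a common mean with
the same slopes — makes incongruent responses *faster* than congruent ones
at moderate `f`, contradicting both facts; we rejected it for that reason.)

**Why there is no separate `|o − f|` term in the emission mean.** Within a
congruency class, `|o − f|` equals `f` (congruent) or `1 − f` (incongruent):
it is an affine function of `f`. A separate coefficient on it is therefore
not identifiable next to the linear-in-`f` mean, which already spans it; the
congruency-specific `(a_c, b_c)` parameterization is complete.

## Fitting

The emission hyperparameters are estimated per subject by an approximate
(generalized) EM: the E-step filters the whole sequence under the current
hyperparameters to obtain the trial-wise `f_hat`; the M-step refits, per
congruency, the least-squares regression of RS on `f_hat` and sets
`sigma_c` to the residual s.d. (floored at 1e-3). Iteration stops when no
parameter moves by more than 1e-4 (at most 100 iterations; typical runs
converge in 4–7). Because the E-step re-filters the entire sequence, the
monitored predictive log-likelihood is not guaranteed monotone; in practice
it rises steeply on the first iteration and any later dips are a few per
cent of the total gain at most. Intercepts are recovered within a few per
cent; slopes sit at the information limit of a 768-trial design (median
relative error ≈ 15–20%, essentially matching an oracle regression on the
true latent conflict path).

The fixed-LR comparators profile out the same emission family: for each
candidate learning rate (or product-grid pair, with run type known to the
two-LR model), RS is regressed on the delta-rule prediction per congruency
and the BIC is computed from the pooled residual variance. The free
parameter counts are 0, 1 and 2 — the emission parameters are profiled out
identically in all three models and therefore excluded everywhere. Ties in
the exhaustive search break towards the smallest learning rate
(lexicographically for two). The product-grid search (491² combinations ×
768 trials per subject) runs in compiled code.

## Group-level model selection

Log model evidence is approximated by `−BIC/2`. The random-effects scheme
treats each subject's generating model as a draw from a population
multinomial with Dirichlet-distributed frequencies, updated by the standard
variational iteration from a uniform Dirichlet(1, 1, 1) prior; exceedance
probabilities are estimated from 1e5 Monte-Carlo draws of the posterior
Dirichlet. Convergence tolerance 1e-6 on the Dirichlet counts, capped at
1e4 iterations (never reached in practice).

## The behavioural GLM

Error, post-error, RT-outlier (> 2.5 s.d. from the subject's mean),
post-outlier and burn-in trials are excluded; the outlier mean and s.d. are
computed over correct-response RTs only, since error trials carry no
meaningful RT. Model estimates for excluded trials are discarded, and the
retained vectors are z-scored *after* exclusion ("normalized" is read as
z-scoring). The design holds seven regressors plus a constant: the three
standardized mains (LR, predicted conflict, congruency), their two-way
products and the three-way product. The conflict-by-congruency column — the
control-prediction-error regressor — is computed as the standardized
unsigned prediction error `|o − f_hat|`, and the three-way column as
`z(alpha) × z(|o − f_hat|)`. This spans the same column space as plain
products of the mains, but aligns the interaction coefficients with the
prediction-error reading: slower responses under larger control prediction
error appear directly as a negative effect, while the congruency main
effect keeps its incongruent-coded sign. (With plain products, one of the
two signs necessarily flips, because the product of z-scored `f` and
incongruent-coded `o` is negatively proportional to `|o − f|` once the
mains are controlled.) Each effect is estimated by residualized regression
— the test column is regressed on the other columns and its residual enters
the RS regression alongside them — which equals the full-model coefficient
by the Frisch–Waugh–Lovell identity (property-tested), and is tested
against zero across subjects with a two-sided one-sample t-test.
Interaction columns are not re-standardized; a second standardization would
rescale coefficients but leave t statistics unchanged. The RS normality
premise is screened per subject with one-sample Kolmogorov–Smirnov tests
against a Gaussian with the sample's own moments, Benjamini–Hochberg
corrected across the congruency conditions.

## What the generator emulates — and what it does not

The synthetic cohort reproduces the design exactly (8 runs of 16 + 4×20
trials; stable runs at 20% or 80% incongruent, volatile runs alternating
every block; exact per-block counts, so the incidence of incongruent trials
is exactly 0.5 within each run class), and the behavioural model's own
emission assumptions: Gaussian RS per congruency with a mean linear in the
latent prediction, i.i.d. errors at 5.8% (accuracy ≈ 94.2%), and injected
slow outliers (1% of correct trials, RT × 3) so the exclusion filter has
real work to do. Per-subject emission parameters are jittered ±10% around
the defaults, and each subject receives a fresh counterbalanced run order.

It deliberately omits: post-error slowing as a generative mechanism (the
behavioural model excludes those trials), sequential RT dependencies beyond
the latent conflict path, stimulus identity (faces, words, response hands),
and any deviation from Gaussian RS. Passing tests on this cohort therefore
demonstrate internal consistency of the pipeline — that the analysis
recovers the structure the generator put in — not that the model fits human
data; the block-exact counts also make the design checks deterministic
where real stimulus streams would be stochastic.

## Numerical choices

* Midpoint grids keep all nodes strictly inside (0, 1); beta-kernel rows are
  evaluated at the nodes and renormalized, so the propagation is a proper
  stochastic matrix on the grid (mass is conserved to 1e-10 and checked).
* Likelihood updates are computed in linear space with per-trial
  renormalization; a Gaussian RS density that underflows across the whole
  grid (possible only for extreme injected outliers) leaves the belief
  unchanged rather than producing 0/0.
* The filter's inner loop stores the belief f-major so congruency and RS
  likelihoods recycle down columns without copies; a test asserts exact
  equality with the explicit operation-by-operation composition.
* Simulated RS is truncated below at 0.1 1/s to keep RT finite; per-trial
  congruency likelihoods in the BIC are floored at 1e-12; residual variances
  at 1e-12.
* The stationary-tracking check averages five independent streams to reduce
  seed noise in what is a long-run property.
* Problem sizes: the full study uses 21 subjects × 768 trials at the 50 × 50
  default grid; property tests use 12–20 node grids where only mechanics are
  at stake.

## Known limitations

* **Tracking bias.** The mode-parameterized beta kernel pulls the conflict
  mean towards 0.5 by `(1 − 2f)/s` per step, so even the slowest trackers
  equilibrate slightly inside the true rate: long-run tracking of a 0.8
  stream plateaus near 0.76–0.78 rather than 0.80. A mean-parameterized
  kernel would remove the bias but would not be the stated model (the mode
  is the previous prediction).
* **Effective learning rate vs. `alpha`.** The regression of prediction
  changes on `alpha_hat × (o − f_hat)` yields a slope of roughly 0.2–0.45,
  not 1: the uniform-jump transition keeps a tail of the posterior spread
  over the whole `alpha` range, inflating `alpha_hat` relative to the
  effective rate, which is itself capped near 0.13 for any single kernel
  width. The RL *form* (sign agreement, positive scaling) holds exactly;
  the unit-slope reading does not, under any mapping we tested.
* **LR–uncertainty coupling.** On data generated by the model itself,
  trial-wise `alpha_hat` and estimation uncertainty share most of their
  variance (r² ≈ 0.8): both are driven by the same posterior-concentration
  dynamics, and the kernel width at the dominant node ties uncertainty to
  `alpha` almost deterministically. The weak coupling reported for human
  data (r² ≈ 0.1) likely reflects noise sources the generator deliberately
  omits; we document rather than reproduce it.
* The EM is approximate (no monotonicity guarantee), fits each subject
  independently, and profiles the emission rather than integrating over it.
* No closed-form or variational alternative to the grid filter is provided;
  run time scales linearly in `n_alpha × n_f²` per trial.
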