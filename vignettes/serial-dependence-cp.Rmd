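---
title: "Serial dependence, slow fluctuations, and choice probability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial dependence, slow fluctuations, and choice probability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialcp)
```

`serialcp` asks a specific question about two-alternative perceptual
decisions: when the spike count of a sensory neuron covaries with the
subject's choice on the same trial (a choice probability, CP, above 0.5),
how much of that covariation is inherited from the previous trial — from the
subject's tendency to repeat or switch choices, from reward, or from slow
drifts in firing rate — and how much is genuinely instantaneous?  This
vignette documents the models, the synthetic data the package tests itself
on, and the numerical decisions a user should know about.

## 1. The session data model

A session couples one unit with an ordered sequence of trials.  Each trial
carries the signed signal strength (fraction of stimulus frames at the
signal disparity; positive values indicate the unit's preferred disparity,
`0` a no-signal trial), the binary choice (1 = preferred-disparity target),
the rewarded target, the reward outcome, the spike count over the 2-s
stimulus, optionally 100-ms binned counts, and optionally the per-trial
histogram of frames over the disparity grid (192 frames = 2 s at 96 Hz).

Analyses are restricted to trials immediately preceded by a completed trial
(`filter_trials()`), because every model uses lag-1 covariates; lags are
computed on the physical trial sequence *before* rows are dropped.  A
session enters population statistics only if its remaining no-signal trials
contain at least four choices of each sign, so that an aROC is defined on
both classes.

All models are fit to signal trials and evaluated on no-signal trials.
No-signal trials carry no net evidence and are rewarded at random, so any
predictability of choice on them reflects internal, not stimulus, signals —
this is the cross-validation scheme used throughout, and it means adding
covariates can *lower* test performance.  Covariates are z-scored with
means and scales taken from the training rows only and applied unchanged to
the test rows; the data do not dictate this split, but computing the
statistics on all rows would leak test information into the fit, so the
conservative choice is made and is visible in `build_design()`'s contract.
Constant columns get scale 1.  The previous spike count is first
residualized on the previous signal strength by least squares through the
origin, removing its stimulus-driven component.

## 2. The choice model

Choices follow a probit GLM, `P(C_n = 1) = Φ(m_n)` with
`m_n = β₀ + Σ_k β_k x_{nk}`, fit by minimizing the mean negative
log-likelihood plus a lasso penalty `λ Σ|β_k|` (intercept unpenalized) with
proximal gradient descent to a KKT residual below 1e-7.  The penalty is on
the *mean* log-likelihood scale, so `λ = 0.025` — the default, selected by
population cross-validation — shrinks weights noticeably at typical session
lengths (~125 training trials) and zeroes genuinely uninformative
covariates; this is what makes null controls come out at exactly zero
weight rather than small noise.  At `λ = 0` the fit coincides with the
unpenalized probit MLE (the suite verifies agreement with `stats::glm` to
1e-4); perfectly separable data are reported with a warning, the weights
then being bounded only by the optimizer's tolerance.

Choice prediction performance (CPP) is the aROC of the fitted model's
scores against realized choices on the held-out no-signal trials, computed
by the rank (Mann–Whitney) statistic with ties counted ½.  Cumulative
analyses add covariates in a stated order and report per-session increments
of the metric with a two-sided Wilcoxon signed-rank test across sessions
(exact for n ≤ 25 without ties, normal approximation otherwise).  Covariate
sets are used exactly as passed: the single-covariate CPPs are models with
that covariate alone, while strategy analyses pass the stimulus explicitly.

CPs and CPPs are converted to **choice correlations** through the
bivariate-Gaussian threshold model: if a spike variable and the decision
variable are standard bivariate normal with correlation ρ and the choice is
the sign of the decision variable, then
`CP(ρ) = E[Φ(ρ(|u|+|v|)/√(2(1−ρ²)))]` with `u, v` standard normal.  The
expectation is evaluated as a one-dimensional adaptive quadrature over the
closed-form density of `|u|+|v|`,
`f(s) = (2/√π) e^{−s²/4} erf(s/2)`, and inverted with `uniroot`; a 1e7
sample Monte-Carlo oracle agrees to better than 1e-3.  The function is odd
around CP = 0.5 and strictly increasing.

The expected drop in proportion correct caused by history-induced variance
σ² of the decision variable is `(π/16)σ²`.  A direct simulation of a
biased probit observer across the default signal levels tracks this
approximation in rank and order of magnitude (the constant depends on where
the stimuli sit on the psychometric function, so only order-of-magnitude
agreement should be expected).

**Psychometrics and the observer control.**  Psychometric functions are
cumulative Gaussians `P(C=1) = Φ((signal − μ)/σ)` fit by probit regression,
optionally split by the previous choice's sign.  The independent-observer
control refits each session's psychometric function, regenerates choices as
`Bernoulli(Φ((signal − μ)/σ))` on the *identical* stimulus sequence, and
re-runs the history GLM.  Because the pseudorandomized design makes
stimulus-sign alternations slightly more likely than 50% (for a balanced
two-sign multiset of size 2m a uniform permutation alternates with
probability m/(2m−1)), this control distinguishes genuine behavioral
history effects from sequence statistics.

## 3. The spike-count model

Spike counts follow a Poisson GLM with exponential nonlinearity.  For slow
fluctuations, a zero-mean Gaussian-process latent with squared-exponential
kernel `amp²·exp(−(Δtrial/τ)²)` is added to the log rate and the model is
fit by alternating maximization: Newton steps for the latent given the
weights (the MAP problem is concave), IRLS for the weights given the
latent.  τ defaults to 35 trials, the population cross-validated value and
the only tuned kernel hyperparameter; the amplitude defaults to 1 in
log-rate units.  Distances use the *original* trial indices, so gaps from
excluded trials are respected.  Held-out trials receive the posterior-mean
latent conditioned on the training-trial latents — the probabilistic
default for an unobserved function value.  Two limits are verified in the
test suite: amplitude → 0 recovers the plain GLM to 1e-6, and τ → 0
decouples the latent into independent per-trial ridge problems.  No
sparsity penalty is applied to spike models.  Prediction performance is the
Pearson correlation between predicted and measured counts on no-signal
trials, defined as 0 when the prediction is constant.

**Time-resolved variant.**  Each trial is split into 20 bins of 100 ms.
The within-trial shape is captured by two PSTH basis functions obtained by
PCA across all unit × condition PSTHs after correcting each unit's response
latency (integer-bin circular shift maximizing cross-correlation with the
population mean; the latency estimator is the package's own choice, as is
treating shifts as circular on the 2-s window).  Each of the behavioral
covariates (current choice, previous choice, previous target, previous win)
enters as four predictors acting on non-overlapping 500-ms epochs; the
stimulus enters at trial level and the basis regressors enter minus the
unit's mean PSTH.  Aliased (collinear) columns are dropped from prediction.
Performance is reported per 500-ms quartile as the correlation of
quartile-summed predicted and measured counts on no-signal trials.

## 4. Semipartial choice probabilities

Because choices are binary, "choice residuals" are hard to define; instead
history is regressed out of the spike counts only (ordinary least squares
with intercept, no cross-validation), and the CP of the residuals against
the untouched choices is the semipartial CP.  Its absolute value
lower-bounds the corresponding partial correlation because the removed
component is orthogonal to the residual.  Counts on no-signal trials are
first corrected for stimulus-induced variability by regressing them on the
per-trial frame histogram (one regressor per disparity level, intercept
included) and keeping residuals plus the grand mean; the histogram columns
sum to a constant, so the system is solved by a rank-revealing QR.  This
linear-in-frame-content correction is a deliberate simplification of the
original procedure for this task, which is not restated in the accessible
text; it removes exactly the linear dependence of counts on frame content,
which is the leakage pathway the generator can produce.

The statistical-interaction ladder asks, for each edge "covariate block →
target given conditioning set", whether adding the block improves held-out
prediction (choice correlation units for choice targets, Pearson cc for
spike targets) at a two-sided Wilcoxon p < 0.05 across sessions.

## 5. The synthetic session generator

The generator's defaults are the study conditions the analyses assume, set
once: 75 units; 252 trials per session of which 126 are no-signal and 21
each carry signals of ±6, ±12.5 and ±25% extra frames, shuffled without
replacement; probit choices with history weights w_choice = −0.275
(switching), w_target = 0.054, w_win = 0.05 on ±1-coded regressors and a
stimulus weight of 4 (≈84% correct at the 25% level); Poisson spike counts
with log-baseline log(40) (≈20 spikes/s), stimulus tuning 2, lag-1 AR
coefficient 0.04 on the standardized previous count, reward gain 0.1, and a
GP with τ = 35 and amplitude 0.1.  The AR and GP amplitudes were fixed by
matching the serial predictability of counts that the analyses are designed
around (previous-count cc ≈ 0.37, slow-fluctuation cc somewhat larger) and
are not revisited per analysis.  The AR input is clipped at ±3 standard
units: a feedback of the standardized realized count through an exponential
link is otherwise explosive for rare large counts, and the clip binds with
probability < 1%.

The instantaneous choice–spike coupling is feedforward by default: the
trial's standardized count enters the decision variable with a weight
chosen so that the implied choice correlation equals a target value,
accounting for the variance the history weights add to the decision
variable; the default target is the choice correlation of CP 0.56 under the
threshold-model conversion.  A feedback variant (choice gain entering the
spike log rate) is a configuration switch.  Because the standardized count
is Poisson-lognormal rather than Gaussian, the realized population CP sits
≈0.005–0.01 above the Gaussian calibration target; this shape effect is
inherent to coupling against an observable count.  Rewards on no-signal
trials are a fair coin.  Every unit draws from its own substream, so
populations are bit-reproducible from one seed.

What the generator does *not* emulate: sub-100-ms spike timing, adaptation
within trials beyond the two-template PSTH mixture, inter-neuron noise
correlations (sessions hold one unit), non-Poisson dispersion, and lapses.
Passing tests therefore certify the statistical machinery on data with the
assumed structure, not the biological fidelity of that structure.

## 6. Autoregressive models and the power analysis

Four single-neuron models formalize where a CP can come from.  With
`cb_t = ±1` the coded choice, latent spike state `s_t`, and standard
Gaussian noises:

* **CM1** (instantaneous feedforward): `s_t = μ + α(s_{t−1}−μ) + σ₂ε_t`;
  `c_t = 1[ω(s_t−μ) + β·cb_{t−1} + σ₁ϵ_t > 0]`.
* **CM2** (post-decision feedback): choice first from history alone, then
  `s_t = μ + α(s_{t−1}−μ) + γ·cb_t + σ₂ε_t`.
* **ICM1** (serial feedback): as CM2 but with `γ·cb_{t−1}`.
* **ICM2** (serial feedforward): `c_t` uses `ω(s_{t−1}−μ)`; `s_t` is a plain
  AR(1).

Counts are emitted as `max(0, round(s_t))`; CP and the fitted
autocovariances are rank/second-moment statistics, insensitive to this
emission at realistic firing ranges.  The threshold rule is invariant to
rescaling the decision equation, so σ₁ is fixed at 1 during fitting — it is
listed as a model parameter but is not identifiable from the fitted
moments.  Each unit's model is fit by minimizing the summed squared
relative mismatch between simulated moments (common random numbers across
evaluations, 20 000 trials per evaluation) and five targets: CP, lag-1
choice autocovariance (±1 coding), lag-1 spike autocovariance, spike mean
and spike variance.  The spike mean and variance are included because the
three headline moments under-determine the parameters; they pin μ and σ₂
without affecting the others.  The optimizer is staged multi-start
Nelder–Mead: the spike chain's (α, σ₂, μ) start at their closed-form
moment-implied values and β at its threshold-chain value, a 2-D search over
(β, coupling) runs first, then the full joint refinement; a derivative-free
evolutionary search would do equally well here, but the staged simplex is
simple and reproducible.  A fit is flagged converged when every relative
mismatch is below 2%.

The power analysis simulates each unit's fitted model at its own no-signal
trial count (defaults near-equal counts totalling 9522 across 75 units),
computes per unit the raw CP and the semipartial CP after regressing the
previous choice and previous count out of the counts, tests the population
mean semipartial CP against 0.5 (one-sample t test) per repetition (default
500), and reports the rejection fraction plus two correlations: raw vs
semipartial CP within the simulation, and the *target* (fitted-to) CPs vs
the simulated semipartial CPs.  The latter is the diagnostic that separates
the model classes cleanly — for serial-pathway models the semipartial CPs
are noise around 0.5 and uncorrelated with the target CPs, while for
instantaneous models they track them.

## 7. Numerical notes and limitations

* aROC is computed by ranks; for the integer counts inside the AR fitting
  loop an equivalent histogram form is used for speed (verified identical).
* Degenerate inputs: constant design columns pass through with scale 1;
  sessions failing the four-choices rule return `NA` population entries;
  constant predictions give cc = 0; all-zero Wilcoxon increments give
  p = 1; GP kernels receive a 1e-6 jitter, escalated before failing.
* Fits with duplicated covariates reach the same optimum only up to the
  solver tolerance; because aROC is a rank statistic, near-tied scores can
  flip, so "adding a duplicate changes nothing" holds to ~1e-3, not
  bit-exactly.
* Test problem sizes: unit tests use 8–16 unit populations (~250 trials per
  session); the benchmark checks use the full 75-unit conditions except the
  AR power benchmark, which runs 20 units × 20 repetitions — sizes chosen
  to estimate each population mean to well within its stated tolerance.
* Sessions are capped at a few hundred trials, so the GP uses dense
  Cholesky factorizations; no low-rank approximations are provided.
* Per-session fits are independent; there is no hierarchical pooling, no
  lapse-rate psychometrics, and no population (multi-neuron) extension of
  the AR models.
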