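# serialcp

Do serial dependencies explain choice probabilities?  During perceptual
decisions the spiking of sensory neurons covaries with the subject's choice
("choice probability", CP), choices depend on the previous trial (serial
dependence), and firing rates drift over many seconds.  `serialcp` provides
the statistical machinery to ask whether the first observation is a
consequence of the other two: history-aware probit choice models, Poisson
spike-count models with a slow latent modulator, semipartial choice
probabilities, an independent-observer control, and autoregressive
choice–spike simulators for a power analysis — together with a synthetic
session generator that emulates pseudorandomized two-alternative disparity
discrimination experiments, so every stage of the pipeline is testable
without recorded data.

It is written for systems/computational neuroscientists analyzing
simultaneously recorded behavior and single-unit spike counts in
two-alternative forced-choice tasks.

## The statistics at the core

* **Choice probability.** For no-signal trials, the area under the ROC
  comparing the spike-count distributions conditioned on the two choices
  (Mann–Whitney statistic, ties counted ½).  `choice_probability()`,
  `area_under_roc()`.
* **Choice prediction performance (CPP).** A probit GLM
  `P(C_n = 1) = Φ(β₀ + Σ β·x)` with lasso penalty `λΣ|β|` is fit to the
  signal trials of a session and scored on its no-signal trials; the aROC of
  the scores against realized choices generalizes CP to arbitrary covariate
  sets (previous choice `C_{n−1}`, previous target `T_{n−1}`, previous
  reward `W_{n−1}`, stimulus `I_n`, spike counts `S_n`, `S_{n−1}`).
  `fit_probit_lasso()`, `choice_prediction_performance()`,
  `cumulative_cpp()`.
* **Choice correlation.** CP mapped to a Pearson correlation under the
  bivariate-Gaussian threshold model,
  `CP(ρ) = E[Φ(ρ(|u|+|v|)/√(2(1−ρ²)))]`, evaluated exactly and inverted
  numerically.  `cp_to_choice_correlation()`.
* **Spike-count models.** Poisson GLM with exponential nonlinearity;
  optionally a Gaussian-process latent with squared-exponential kernel
  `exp(−(r/τ)²)` (default τ = 35 trials) captures slow firing-rate
  fluctuations; a 20 × 100-ms time-resolved variant uses per-epoch history
  predictors and a two-component PSTH basis.  `fit_poisson_glm()`,
  `spike_prediction_cc()`, `psth_basis()`, `fit_time_resolved()`.
* **Semipartial CP.** History is regressed out of the spike counts only
  (choices stay binary); the residual CP lower-bounds the corresponding
  partial correlation.  `semipartial_cp()`, `cp_summary()`.
* **Autoregressive models.** Four single-neuron simulators in which CP
  arises from instantaneous coupling (CM1 feedforward, CM2 feedback) or
  purely serial pathways (ICM1: previous choice → spikes; ICM2: previous
  spikes → choice), moment-matched to per-unit statistics and used for a
  500-repetition semipartial-CP power analysis.  `simulate_ar()`,
  `fit_ar()`, `power_analysis()`.

## Worked example

```r
library(serialcp)

# a synthetic population: 75 units x 252 trials, switching choice strategy
# (previous-choice weight -0.275), instantaneous coupling giving CP ~ 0.56
pop <- generate_population(sim_config(n_units = 75, seed = 1))
trials <- filter_trials(pop$trials)

# spike count alone predicts choices on held-out no-signal trials
cpp <- choice_prediction_performance(trials, "spikes", lambda = 0.025)
mean(cpp$cpp, na.rm = TRUE)
#> [1] 0.5678003

# raw versus semipartial CP: removing choice history barely moves CP
cps <- cp_summary(pop$trials)
colMeans(cps[, c("raw_cp", "semipartial_cp_history", "semipartial_cp_choice")])
#>                 raw_cp semipartial_cp_history  semipartial_cp_choice
#>              0.5668178              0.5543714              0.5004936
```

The spike count alone predicts held-out choices at ~0.57 (well above the
0.5 chance level); regressing choice history out of the counts leaves the
CP essentially unchanged (0.554 vs 0.567), while regressing out the current
choice — a positive control — collapses it to chance.  That is the
signature of instantaneous, not serial, choice–spike coupling.

```r
# power analysis: can the semipartial analysis detect a serial origin?
stats <- synthetic_unit_stats(75, seed = 2)
fits <- lapply(seq_len(75), function(i) fit_ar("ICM1", stats[i, ], seed = i))
pw <- power_analysis(fits, power_trial_counts(75, 9522), reps = 500, seed = 3)
mean(pw$mean_semi_cp); attr(pw, "reject_fraction")
```

For the serial-pathway (ICM) models the mean semipartial CP returns to 0.5
and the null hypothesis "mean semipartial CP = 0.5" is rarely rejected; for
the instantaneous (CM) models it is rejected in essentially every
repetition.

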