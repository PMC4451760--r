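# fisherbc

Direct, bias-corrected estimation of linear Fisher information in
correlated neural populations.

## What problem this solves

Given spike counts of `N` simultaneously recorded neurons over `T` trials
in each of two stimulus conditions separated by `dθ`, the reliability of
the population code is summarized by the linear Fisher information

    I = f'ᵀ Σ⁻¹ f'        (units dθ⁻², e.g. deg⁻²)

with `f'` the tuning-curve derivative and `Σ` the noise covariance.
Plugging the empirical moments straight into this formula overestimates
`I` badly when `T` is not much larger than `N` (the covariance is
inverted, the derivative squared — both non-linear), while the
traditional cross-validated decoder *under*estimates it. `fisherbc`
implements the unbiased direct estimator

    Î_bc = (dμ/dθ)ᵀ S⁻¹ (dμ/dθ) · (2T−N−3)/(2T−2) − 2N/(T·dθ²)

(inverse-Wishart correction of the inverted pooled covariance plus a
derivative-noise correction), its closed-form sampling variance, and the
companion estimators `Î_shuffle` (independent population with the same
marginals), `Î_AB` (decoder optimized for dataset A, read out on dataset
B) and `Î_diag` (correlation-blind decoder), together with:

* an early-stopping cross-validated linear decoder baseline
  (`decoder_pipeline()`),
* generative population models with analytic ground truth — an exact
  multivariate Gaussian, a doubly stochastic Gabor filter-bank V1 model
  with information-limiting correlations, and a Von Mises–Poisson
  low-count model,
* a reproducible sweep harness (`run_sweep()`, `bootstrap_bands()`,
  `subsample_trials()`) for estimator-accuracy comparisons across `T`
  and `N`.

It is aimed at systems/computational neuroscientists quantifying coding
reliability, the impact of noise correlations, or changes in encoding
across conditions, from finite recordings (usable whenever
`T > (N+2)/2`; variance finite for `T > (N+5)/2`).

## Worked example

```r
library(fisherbc)

# V1-like model population: 50 Gabor-filter neurons, orientations {-7, 0} deg
pop <- gabor_population(N = 50, gain = 30, seed = 1)
gt  <- ground_truth(pop)
gt$info_true
#> [1] 0.2847551

# one simulated experiment: 250 trials per condition
ts <- simulate_experiment(pop, T = 250, seed = 7)

bc_info(ts)
#> Linear Fisher information (bias_corrected): 0.299559  [analytic SD 0.025]
#>   T = 250 trials/condition, N = 50 neurons, dtheta = 7

decoder_pipeline(ts, seed = 7)$validation
#> Linear Fisher information (decoder_validation): 0.239481
#>   T = 83 trials/condition, N = 50 neurons, dtheta = 7

bc_info_shuffle(ts)
#> Linear Fisher information (shuffle): 0.840539
#>   T = 250 trials/condition, N = 50 neurons, dtheta = 7
```

Reading the numbers: the true information of this model population is
0.285 deg⁻². From a single 250-trial experiment the direct bias-corrected
estimate lands at 0.300 ± 0.025 (the error bar is the analytic sampling
SD), while the early-stopping decoder — which must split the same data
into training/test/validation thirds and stops while still suboptimal —
reads out only 0.239 on its validation third. The shuffled information
(0.84) is about three times the actual information: the model's
correlations are information-limiting, as its input-image bound
(`gabor_input_info(pop)` = 0.469) confirms. A percent-correct translation
is available: `info_to_percent_correct(0.2996, 7)` → 97.2% correct for a
7-degree discrimination.

Across 200 such experiments the direct estimator's relative error
(√MSE / I) is about 8%, versus about 14% for the decoder; the decoder
needs ~1000 trials to match the direct estimator at 250 (see below).

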