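# poptune

Noise-corrected population tuning analysis for auditory neural recordings.

## The problem

Along the auditory pathway — cochlear nucleus (CN), inferior colliculus
(IC), auditory cortex (AC) — the activity patterns that different sounds
evoke in a neural population become progressively less similar
("decorrelation"). Measuring this with raw Pearson correlations between
trial-averaged population vectors is misleading: trial-to-trial
variability attenuates every correlation toward zero, and the attenuation
differs between regions and recording techniques (Neuropixels spikes vs
two-photon calcium imaging), so regions cannot be compared directly.

`poptune` implements the split-half **noise-corrected Pearson
correlation**. Trials of each sound are split into two random halves; the
similarity between two sounds *s* and *s′* is estimated as

ρ̂(s, s′) = ⟨ρ(v̄ₛ, v̄ₛ′)⟩ / √(r̄ₛ · r̄ₛ′)

where the numerator averages the Pearson correlations between half-mean
population vectors of the two sounds, and r̄ₛ = ⟨ρ(v̄ₛ⁽¹⁾, v̄ₛ⁽²⁾)⟩ is the
split-half reliability of sound *s*. Splits are redrawn 20 times, the
numerator and the two reliabilities are averaged separately, the ratio is
clipped to [−1, 1], and noise-dominated pairs (mean reliability ≤ 0) are
marked undefined rather than clipped. Population vectors are either
**spatial** (time-averaged response per neuron) or **spatio-temporal**
(all time bins concatenated), over the window from sound onset to 100 ms
after offset.

Around the estimator the package provides the full workflow:

- **stimuli** — synthesis of the calibrated 307-sound battery (pure
  tones, intensity ramps, chords, chirps, colored noises, AM sounds,
  complex-sound surrogates with component decompositions), with 10-ms
  cosine gating and RMS calibration in dB SPL (`build_catalog()`,
  `synthesize()`).
- **preprocess** — ΔF/F with neuropil subtraction and sliding-percentile
  baseline, linear deconvolution r(t) = f′(t) + f(t)/τ, trial extraction
  with baseline subtraction, reliability-based unit selection, and
  virtual-population pooling with trial shuffling (`dff()`,
  `deconvolve()`, `extract_trials()`, `select_reliable_units()`,
  `pool_virtual_population()`).
- **similarity** — the estimator and full RSA matrices
  (`noise_corrected_similarity()`, `rsa_matrix()`, `mean_similarity()`).
- **tuning** — distance-binned population tuning curves, matched-pair
  contrasts (intensity, direction, identity), summed-component linearity
  tests, component-based response reconstruction, category salience, and
  paired Wilcoxon region statistics.
- **periphery** — mouse cochlear map (tonotopy x = −56.5 + 82.5·log₁₀CF,
  innervation N(x) = −0.0038x² + 0.375x + 7.9, spontaneous rate
  SR = 91.1·τ_Ca^2.66) and a simplified phenomenological auditory-nerve
  simulator (`build_cochlear_map()`, `simulate_anf_responses()`).
- **synthpop** — synthetic populations with known ground-truth
  similarity structure and an estimator-validation suite
  (`generate_population()`, `estimator_validation_suite()`).
- **pipeline** — `run_pipeline()` orchestrates catalog → populations →
  RSA → tuning with derived per-stage seeds and a JSON provenance log.

## Worked example

Three synthetic "region-like" populations with progressively sharper
frequency tuning, analysed with the identical pipeline:

```r
library(poptune)
catalog <- build_catalog(seed = 1)
tones <- catalog[catalog$category == "pure_tone" & catalog$level == 70, ]
res <- run_pipeline(list(
  out_dir = "demo", seed = 42, catalog = tones,
  regimes = c("CN", "IC", "AC"), n_units = 100, noise = 50,
  code = "spatial", n_resamples = 20, analyses = "tones"))
```

Output (mean noise-corrected similarity over all 91 tone pairs):

```
CN: mean pairwise similarity 0.161 +/- 0.068 (n = 91 pairs)
IC: mean pairwise similarity -0.018 +/- 0.052 (n = 91 pairs)
AC: mean pairwise similarity -0.056 +/- 0.026 (n = 91 pairs)
```

The broadly tuned CN-like population keeps tone representations
correlated; the sharply tuned AC-like population decorrelates them — the
ordering the estimator is designed to expose despite Poisson trial
noise. The AC-like frequency tuning curve drops steeply with octave
distance:

```
  bin        mean         sem n_pairs
 0.40  0.51090441 0.035269907      13
 0.75 -0.01381717 0.013121702      12
 1.15 -0.15186287 0.009817521      11
 1.50 -0.17077984 0.007016807      10
```

(`bin` is the pair frequency distance in octaves; `n_pairs` the number of
tone pairs at that grid distance.)

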