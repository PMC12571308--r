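---
title: "Noise-corrected population tuning: model, estimator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-corrected population tuning: model, estimator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poptune)
```

## The measurement problem

A population of N neurons represents a sound s as a vector of responses.
Representational similarity analysis (RSA) summarises tuning without a
response model: the similarity matrix over all sound pairs, using the
Pearson correlation between population vectors. Two codes are supported:
the *spatial* code (each neuron's response time-averaged over the
analysis window, vector dimension N) and the *spatio-temporal* code (all
time bins concatenated, dimension N × T). The analysis window runs from
sound onset to 100 ms after sound offset; spatio-temporal bins are 5 ms
for spike data and 43.5 ms for imaging data.

Trial-to-trial variability biases raw correlations toward zero, and the
bias depends on the recording technique and the number of neurons, so
raw values cannot be compared across datasets. The estimator used here
removes the attenuation:

1. Trials of each sound are split into two random halves (an odd trial
   count assigns the extra trial to either half with probability 1/2).
2. For a pair (s, s′) with half-means a, b (sound s) and c, d (sound
   s′), the cross term is the mean of ρ(a,c), ρ(a,d), ρ(b,c), ρ(b,d),
   and the reliabilities are ρ(a,b) and ρ(c,d).
3. Splits are redrawn 20 times. The cross term and each reliability are
   averaged **separately** across resamples and the estimate is
   mean-cross / sqrt(mean-rel_s × mean-rel_s′). Averaging the numerator
   and denominator before taking the ratio is markedly more stable than
   averaging per-resample ratios, whose denominators can pass near zero;
   this choice is recorded in the output metadata
   (`combine = "ratio_of_means"`).
4. The estimate is clipped to [−1, 1]. If either mean reliability is
   ≤ 0 the representation is noise-dominated; clipping such a ratio
   would fabricate ±1, so the pair is instead marked *undefined* (`NA`)
   and excluded (with reported n) from all downstream averages.
   Zero-variance half-average vectors drop the affected resample terms.

Working with half-means rather than single trials also limits the
influence of within-trial noise correlations between simultaneously
recorded neurons; `pool_virtual_population()` additionally shuffles
trial identity per (unit, sound) when sessions are merged, which breaks
residual noise correlations by construction.

### Matrix evaluation

`rsa_matrix()` draws, per resample, one split-half partition per sound
shared by all pairs in the matrix (marginally equivalent to independent
per-pair partitions, but allowing all pairwise correlations to be
computed as single matrix operations), plus a second independent
partition per sound used for the diagonal. Self-similarity computed
between two independent partitions of the same sound is ≥ 1 before
clipping (the partitions share trials, so their noise is positively
correlated), hence the diagonal is exactly 1 after clipping whenever the
sound's reliability is positive — the intended calibration point.
`noise_corrected_similarity()`, the single-pair entry point, draws its
own partitions per pair.

### Validation

`estimator_validation_suite()` generates matched pattern pairs with a
known correlation (default study condition: N = 500 units, R = 12
trials, pattern correlation 0.5, Gaussian trial noise with SD √8 of the
pattern SD, which places the naive trial-averaged correlation near 0.3)
and measures bias and RMSE of the corrected and naive estimators against
the realised ground truth. Under these conditions the corrected
estimator's mean bias over 50 seeds is within ±0.05 while the naive
estimator underestimates by ≈ 0.2. With very small populations
(N < 50) the corrected estimator's variance grows visibly; the report
flags these conditions.

## The stimulus battery

`build_catalog()` enumerates 307 sounds in eight categories
(28 tones / 26 ramps / 48 chords / 20 chirps / 30 noises / 48 AM /
60 complex / 47 decomposition). All waveforms are pressure in Pascals,
cosine-gated over 10 ms at onset and offset, and RMS-calibrated in
dB SPL (re 20 µPa); calibration is applied after gating so the measured
RMS matches the target exactly. Where the protocol fixes only part of a
category, the remaining choices were made once and are listed here:

- **Durations**: tones and chords 200 ms; ramps, noises, AM and complex
  sounds 500 ms; chirps as listed (25–400 ms and 500 ms). The protocol
  bounds durations at 500 ms without printing every value.
- **Tone grid**: 14 frequencies log-spaced inclusive of 2 and 60 kHz;
  the 13 ramp frequencies are the 13 grid tones below 50 kHz.
- **Chords**: the low/mid/high pools use all 11 subsets of size 2–4 of
  their 4 frequencies; the broad pool uses the 10 subsets of size 2–3;
  5 harmonic subsets of (4, 8, 12, 16) kHz. Component phases are random
  uniform, drawn from the catalog seed and stored. A chord sums k
  per-component-calibrated tones, so its total RMS is the stated level
  + 10·log₁₀k dB (incoherent sum).
- **AM**: 6 modulation frequencies log-spaced 4–160 Hz × 8 carriers
  (2 grid tones, the 5 harmonic chords, 1 broadband noise); 100% depth
  with envelope (1 − cos 2π·fm·t)/2 so modulation starts at zero phase.
- **Noises**: band-pass filtering is an 8th-order Butterworth magnitude
  response (order-4 design run forward–backward, zero-phase). The 14
  band-filtered noises are 9 nested bands (0.5–4.5 octaves in 0.5-octave
  steps around the geometric centre of 2–80 kHz) — giving 8 pairs at
  0.5-octave bandwidth difference down to 3 pairs at 3 octaves — plus 5
  one-octave bands at different centres.
- **Chirps**: exponential (log-frequency) sweeps; each down-chirp is the
  exact time reversal of its up counterpart, making direction contrasts
  exact by construction. The sweep-direction contrast uses the five
  500-ms frequency-content sweep pairs.
- **Complex sounds**: synthetic surrogates replace natural recordings
  that cannot be redistributed. Each of 15 identities is a program of
  parameterised components (fast chirps, click trains, chirp trains,
  band noises, harmonic FM stacks) with stored onsets. The first four
  identities use fixed decomposable programs with 5/10/13/15 components
  — chosen so components plus the four reconstructions total 47 catalog
  entries — and component amplitudes are baked in at build time so each
  reconstruction is sample-wise identical to the sum of its components
  and to the forward 70-dB parent.

## Preprocessing

ΔF/F subtracts 70% of the neuropil signal, takes F₀ as the sliding 3rd
percentile of a Gaussian-filtered corrected trace, and divides. The
percentile window is 60 s and the pre-filter σ is 2 s — much longer than
a calcium transient, much shorter than session drift; neither length is
dictated by the data format, so both are exposed as arguments. Units
with non-positive F₀ anywhere are flagged invalid rather than silently
producing NaNs. Deconvolution uses r(t) = f′(t) + f(t)/τ with τ = 2 s,
central differences in the interior (one-sided at the ends), and
Gaussian smoothing with σ = 31 ms, truncated at ±4σ with reflective edge
handling (so constants are preserved). This removes the indicator decay
but not its rise time.

Trial extraction windows are −0.2→0.8 s (imaging, baseline
−0.2→−0.02 s) and −0.3→1.0 s at 1-ms bins (spikes, baseline −0.3→0 s),
with each trial's baseline mean subtracted. The reliability screen
averages Pearson correlations over all trial pairs of the binned
temporal response (5-ms bins, threshold 0.05 for spikes; 42-ms bins,
threshold 0.3 for imaging), using the full extracted window;
correlations undefined through zero variance count as 0, which is
conservative toward rejection. The two printed imaging bin widths (42 ms
for the reliability screen, 43.5 ms for spatio-temporal vectors) are
kept as two distinct parameters.

## Cochlear periphery

The geometry formulas are exact closed forms: position
x = −56.5 + 82.5·log₁₀(CF) (% from apex, CF in kHz), innervation
N(x) = −0.0038x² + 0.375x + 7.9 fibers per IHC (rounded to the nearest
integer), spontaneous rate SR = 91.1·τ_Ca^2.66 (τ_Ca in ms). The default
map tiles 40 IHCs at 12 per octave from 5 kHz (1.17% to 81.9% in 2.07%
increments). Note an internal inconsistency of the published description
that the formulas cannot reproduce: the quoted base position 83.9% and
coverage 82.8% differ slightly from the formula values (x(50 kHz) =
83.7%), and no nearest-integer rounding of N(x) over this grid sums to
the quoted total of 691 fibers (the maximum attainable is ≈ 686). The
package reports the formula values. Per-fiber τ_Ca is drawn log-uniformly
over the interval mapping to SR ∈ [0.5, 95] spikes/s; only the SR range
is published, not the distribution.

`simulate_anf_responses()` is a deliberately simplified phenomenological
chain, not a biophysical cascade: gammatone band-pass at CF (bandwidth
CF/8), half-wave rectification with power-law compression (exponent
0.4), one-pole envelope low-pass (τ = 1 ms), divisive exponential
adaptation (τ = 100 ms), a saturating driven rate (250 spikes/s maximum,
half-saturation at a 40-dB-SPL channel envelope) added to the fiber's
spontaneous rate, and inhomogeneous Poisson spiking in 1-ms bins. It
reproduces tonotopic selectivity, adaptation and spontaneous activity —
enough for the qualitative "blurred tonotopic" RSA structure of the
auditory nerve — but not two-tone suppression, middle-ear filtering or
refractoriness.

## Synthetic populations and what they do (not) show

`generate_population()` gives each unit a log-Gaussian frequency tuning
curve (centre log-uniform over 2–60 kHz, width set by the regime:
CN-like 1.5 octaves, IC-like 0.6, AC-like 0.25, with 20% log-normal
spread), optional AM band-pass tuning and direction selectivity,
a monotonic intensity gain (level/70)^γ with γ ∈ [0.5, 1.5], optional
per-category gains, and an alpha-function onset kernel (latency
10–50 ms, τ 30–100 ms). Trial noise is Poisson on counts (spike-like;
the `noise` parameter is the peak driven rate in spikes/s, so higher
values mean *less* relative noise) or additive Gaussian on deconvolved
bins (imaging-like). The exact noiseless tensor and its similarity
matrices accompany every draw, so the whole pipeline can be checked
against ground truth: noiseless tensors reproduce the ground-truth RSA
to 1e−10, and progressively sharper regimes yield strictly decreasing
mean pairwise similarity.

The `linear_compound` switch disables all multiplicative response
modulation and makes amplitudes exactly additive over stimulus frequency
components, so summed-component similarity is exactly 1 — the positive
control for the linearity analyses. Without the switch, multi-component
amplitudes are normalised by √k (sublinear), the realistic negative
control.

What passing these tests shows: the estimator, windowing, binning and
pair bookkeeping are correct, and the pipeline recovers known
representational geometry under realistic Poisson/Gaussian noise at the
study's trial count (R = 12). What they do not show: real neural
response diversity (multi-peaked tuning, offset responses, adaptation
across trials), noise correlations beyond the shuffle-removable kind,
or any claim about real CN/IC/AC values — region-level numbers from
recorded data require the original datasets, which the package does not
ship.

## Problem sizes and numerical choices

Test and validation runs use deliberately modest sizes — 14–28 sounds,
25–150 units, 12 trials, 20 split resamples, 10–50 seeds — chosen so the
whole suite completes in about a minute while keeping every statistical
margin (estimator bias ±0.05, strict regime ordering per seed) far above
its Monte-Carlo error. Octave distances on the tone grid are snapped to
the nearest 0.05 octave before binning (grid arithmetic in floating
point otherwise fragments bins); the smallest tone-grid step is ≈ 0.38
octave, so "fine tuning" summaries are reported at that true distance
rather than a nominal 0.3. Salience profiles evaluate each category at
the reference level (70 dB SPL) where the category has entries at it, so
the reference category maps to 1 exactly. Seeds for every stochastic
stage are derived deterministically from a global seed and the stage
name, keeping streams independent and reruns bit-identical.
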