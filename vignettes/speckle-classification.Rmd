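---
title: "Classifying stimulus-evoked surface vibrations from laser speckle video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying stimulus-evoked surface vibrations from laser speckle video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specklesense)
```

## The measurement principle

When coherent laser light reflects off a rough surface (here, skin over a
brain region), the back-scattered waves interfere into a *secondary
speckle pattern*. Observed with a defocused camera in the far field, that
pattern behaves as a rigid interference texture: when the surface tilts
by a small angle, the whole pattern translates on the detector, while
axial and purely transverse surface motion leave it essentially in place.
Tracking the pattern's translation frame to frame therefore reads out a
time series of surface tilt — a remote vibrometer with micro-radian
sensitivity.

Two geometric conditions make this work, both available as calculators:

* **Far-field condition** (`far_field_threshold()`): the observation
  distance must satisfy $Z_2 > D^2 / 4\lambda$, where $D$ is the laser
  spot diameter and $\lambda$ the wavelength. For a 2 cm spot of 532 nm
  light this threshold is ~188 m for the *pattern-formation plane*; in
  practice the defocused-imaging arrangement observes a plane where the
  condition holds, and the calculator lets users check their own
  geometry.
* **Resolved-speckle condition** (`required_focal_length()`): each
  speckle grain of transverse size $\lambda Z_2 / D$, magnified by
  $F / Z_3$, must cover at least $K$ detector pixels, giving
  $F = K \, \Delta x \, Z_3 \, D / (Z_2 \lambda)$. We adopt this grouping
  because it is the only one consistent with far-field speckle scaling: a
  larger spot makes smaller grains and therefore demands a *longer* focal
  length.

## What the simulator emulates — and what it does not

No public recordings exist for this sensing problem, so the package
ships a physics-based generator that stands in for them. A video is
produced in three layers:

1. **Optics.** A square phase screen of i.i.d. uniform $[0, 2\pi)$
   phases models surface roughness. The rendered frame is
   $|\mathcal{F}\{P \, e^{i\varphi}\}|^2$, the far-field intensity of a
   circular pupil $P$ carrying that phase. Translation is applied in the
   transform domain (a linear phase ramp), which is exact at subpixel
   resolution and cyclic. This reproduces *fully developed speckle*:
   negative-exponential intensities with contrast 1. The pupil diameter
   as a fraction of the render field (`pupil_fraction`) sets the speckle
   grain size, roughly `1/pupil_fraction` pixels; the default 0.25 gives
   ~4-px grains, a good regime for subpixel correlation tracking.
2. **Physiology-like signal.** Each (smell, region) pair maps to a tilt
   time series: a sum of two sinusoidal components at class-specific
   frequencies, a cardiac-like pulse train (default 1.8 Hz, the resting
   heart-rate range of a calm dog), and Gaussian tilt noise, all
   attenuated by a distance-dependent gain. The default class table
   gives each smell a distinct frequency pair between 5 and 60 Hz
   (alcohol 8/35, marijuana 14/42, menthol 22/48, garlic 28/56 Hz) and
   the control class no odor component at all; region scales amplitude
   (amygdala 1.0, olfactory bulb 0.6, hippocampus 0.35). These choices
   make the qualitative region ranking reproducible *as a synthetic
   scenario* — they are a modelling device, not a biological claim, and
   a passing pipeline demonstrates parameter recovery on this scenario,
   not performance on real recordings.
3. **Sensor.** Tilt couples to pattern translation through a gain `g`
   (default 0.5 px per micro-radian; the paper-level physics fixes only
   proportionality, so the constant is exposed as configuration).
   Frames are scaled to 8- or 16-bit DN and degraded by Gaussian read
   noise (default 2 DN) and optional Poisson shot noise.

Not modelled, deliberately: speckle decorrelation ("boiling"), fur and
tissue scattering, near-field (Fresnel) propagation, hemodynamic
waveform realism, and motion other than pure tilt. Real recordings
contain all of these, so synthetic results are an upper bound on
tracker fidelity, not a claim about animals.

### A note on testing the intensity statistics

The negative-exponential law holds per pixel at any grain size, but
neighbouring pixels are correlated over one grain. A Kolmogorov–Smirnov
test that assumes independent samples is therefore run on frames
rendered with `pupil_fraction` near 1 (grain ≈ 1 px, pixels effectively
independent) and 16-bit depth (quantization step ≪ the distribution
scale). This controls the test's sample-correlation assumption; the
default tracking configuration keeps the coarser 4-px grains.

## Tracking and features

`estimate_shift()` computes the zero-mean normalized cross-correlation
of two frames in the Fourier domain and refines the peak per axis with
3-point parabolic interpolation — accurate to a few hundredths of a
pixel at the default SNR. Mean removal makes it insensitive to global
illumination drift. `track()` accumulates consecutive-frame shifts
(`sequential`, the default, robust to slow pattern change) or
correlates everything against frame 1 (`anchored`); no drift correction
is applied beyond optional detrending of spectra.

Traces are cut into non-overlapping 40-frame chunks (200 ms at
200 FPS), the classification unit. Each chunk yields a fixed 52-feature
vector: for each of `pos_x`, `pos_y`, `dpos_x`, `dpos_y` — mean, SD,
RMS, min, max, range, energy, dominant frequency, spectral centroid,
and band powers over 0–10, 10–30, 30–60, 60–100 Hz. The `dpos`
channels are the first differences of the chunk's own `pos` samples, so
chunks never borrow information across video or chunk boundaries.
Spectral features use mean-removed, Hann-windowed samples; with 40
samples at 200 FPS the frequency resolution is 5 Hz, a documented
limitation — two class components closer than one bin are not
distinguishable by the spectral features alone, which is why the
default class table spaces components at least 6 Hz apart. A fixed
schema was chosen over an open-ended feature library: reproducibility
of the exact column set matters more here than breadth.

## The classifier

The core model is a from-scratch second-order gradient-boosted tree
ensemble with softmax multi-class coupling. Each boosting round fits
one regression tree per class to the gradient $g_i = p_c - 1[y_i = c]$
and Hessian $h_i = p_c (1 - p_c)$ of the multi-class log loss. Split
search is exact greedy over midpoints of adjacent sorted feature
values, scored by the structure-score gain
$$\tfrac{1}{2}\left[\frac{G_L^2}{H_L + \lambda} +
\frac{G_R^2}{H_R + \lambda} - \frac{G^2}{H + \lambda}\right] - \gamma,$$
and leaves carry the closed-form optimal weight
$w^* = -G/(H + \lambda)$. There is no row/column subsampling, no
histogram binning and no missing-value routing: exact greedy keeps the
implementation equal to a brute-force split oracle on small problems,
which the test suite exploits. Ties in gain break toward the lowest
feature index and lowest threshold, making fits invariant to row
permutation. Defaults (learning rate 0.1, depth 4, $\lambda = 1$,
$\gamma = 0$, 100 rounds, minimum child Hessian $10^{-3}$) are ordinary
boosted-tree practice; the source protocol reports no tuned values, so
these are starting points for the tuner rather than claims.

The training log records the regularized objective (log loss plus
$\gamma T + \tfrac{1}{2}\lambda \sum w^2$ over the applied, shrunken
leaf weights) each round; on every fixture in the test suite it is
non-increasing. Models serialize to JSON at 17 significant digits and
reload bit-stably.

## Hyperparameter search

`tune()` implements a deliberately simplified, TPE-style sampler: after
10 random startup trials the history splits into the best 25% ("good")
and the rest; independent 1-D Parzen densities are fitted per
parameter (log-space for log-scaled domains), each mixed with one
uniform-prior pseudo-observation and given a floor bandwidth of 1/20 of
the domain span — without the prior and the floor the sampler collapses
into a pure exploiter that crawls toward the optimum; 24 candidates
drawn from the good density are scored by the summed log density ratio
and the best is evaluated. No multivariate
modelling, pruning or parallelism — the goal is a reproducible,
dependency-free sampler that demonstrably beats random search on
separable objectives, not a clone of any framework. The pipeline's
tuning objective is validation macro-F1, maximized.

## Splits, evaluation and aggregation

Videos — never chunks — are the unit of assignment: per dog, video tags
are shuffled and allocated by cumulative fraction with
largest-remainder rounding, so 10 videos at 80/20 give exactly 8 + 2.
The protocol names train/validation/test but quantifies only "80/20";
the package defaults to 80/20 train/validation and switches to
70/15/15 when a test partition is requested, reporting which partition
was evaluated. Chunks inherit their video's partition, which is the
leakage guard: two chunks of one video can never face each other across
the train/evaluation boundary.

Metrics follow the classical confusion-matrix definitions: accuracy
$(TP+TN)/n$, precision $TP/(TP+FP)$, sensitivity $TP/(TP+FN)$,
specificity $TN/(FP+TN)$, $F_1 = 2PR/(P+R)$, computed one-vs-rest per
class. Multi-class summaries use **unweighted macro averaging** — the
source protocol never states its averaging scheme, so this choice is
surfaced prominently rather than buried. Zero-denominator metrics are
flagged undefined, never silently coerced to 0 (coercion would inflate
specificity on absent classes). Row-normalized confusion matrices give
each true class "1.00 samples"; all-zero rows stay zero and are
flagged. Reports round to 2 decimals; CSVs keep full precision.

The orchestrator trains one model per (region × distance) cell,
mirroring the per-region analyses, and `aggregate_by_region()` pools
chunks across dogs before splitting for the dog-agnostic analysis. The
control class is included by default and toggleable, since its
reliability differed between the per-dog and pooled analyses in the
source protocol.

## Numerical and degenerate-input choices

* Correlation of a constant (zero-variance) frame is an error, not a
  zero — a silent 0 would fake a perfectly still surface.
* Parabolic refinement falls back to the integer peak when the 3-point
  neighbourhood is not concave or the sub-step exceeds 0.5 px.
* Spectral centroid of an all-zero (or DC-only) series is 0 by
  contract; spectra are energy-normalized so Parseval holds exactly
  under a rectangular window.
* Tilt components at or above Nyquist raise an aliasing error rather
  than fold silently.
* Per-video seeds derive from the master seed by
  `seed + 7919 * counter (mod 2^31 - 1)` over a fixed enumeration
  order, so a dataset is reproducible from `(design, master_seed)`
  alone and all seeds stay within R's integer range.
* Renders keep a guard band of at least half a frame on each side
  (default: 512-px field for 224-px frames); a tilt that would push the
  crop outside the band is a configuration error.

## Problem sizes in the shipped tests

The generator's defaults are the study protocol (224×224 @ 200 FPS,
5 s × 4 repeats, 4 dogs × 3 regions × 5 smells × 2 distances). The test
and acceptance runs exercise the same code on smaller instances chosen
as reasonable desk-scale versions: 1-s single-repeat videos, 2–3 videos
per cell, one region, and — for the amplitude-sweep and
distance-effect properties — 112-px frames on a 256-px field. The
end-to-end checks ask for ≥ 0.90 held-out accuracy on the separable
default scenario, chance-level (0.2 ± 0.1) accuracy after label
shuffling, and amplitude-monotone accuracy across weak/default/strong
signal scales; all three are recomputed, not asserted.

## Known limitations

* Synthetic separability is designed in; nothing here estimates how
  separable real canine recordings are.
* Sequential tracking integrates small biases over long videos; the
  anchored mode avoids that but assumes no pattern decorrelation.
* The 5 Hz spectral resolution of 40-frame chunks limits how close
  class frequency signatures may sit.
* The TPE-style sampler models parameters independently; strongly
  interacting hyperparameters would need a multivariate extension.
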