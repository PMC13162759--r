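---
title: "Tracking continuous arousal with annotations, pupillometry and EEG oscillations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking continuous arousal with annotations, pupillometry and EEG oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(narousal)
```

## The problem this package addresses

During naturalistic viewing — a film, a narrative — emotional arousal
fluctuates continuously, and three very different signals track it: the
viewer's own continuous arousal ratings (0–250 visual-analogue scale,
sampled at 1 Hz), pupil diameter (an autonomic arousal read-out at 60 Hz,
heavily contaminated by screen luminance and blinks), and band-limited
EEG power (delta, theta, and the individual low-alpha band). `narousal`
implements the full analysis chain linking these signals:

1. **Pupil cleaning** — spike removal, blink interpolation, median
   filtering, a missing-data exclusion gate, resampling to 1 Hz,
   luminance regression and Gaussian smoothing.
2. **Group trajectories** — per-subject z-scoring and group averaging of
   annotation and pupil series, and their cross-modal correlation.
3. **Inter-subject correlation (ISC)** — pairwise Pearson correlations
   across subjects, Fisher-z averaged, with a circular time-shift
   surrogate null.
4. **Spectral parametrization** — Welch spectra decomposed into an
   aperiodic 1/f component plus Gaussian peaks,
   $S(f) = L(f) + \sum_n G_n(f)$ with $L(f) = b - \chi \log_{10} f$;
   flattened spectra, individual alpha frequency (IAF), a paired
   rest-vs-movie exponent contrast, and a frequency-bin cluster
   permutation contrast.
5. **Band-power coupling** — 1 s epoch band power, log-transformed,
   smoothed (40 s Gaussian window) and z-scored, correlated with the
   group arousal trajectory via the dot-product statistic
   $r = \mathbf{x}^\top \mathbf{y} / (N-1)$ on z-scored vectors, which is
   identically the Pearson correlation.
6. **Cluster statistics** — per-channel one-sample t-tests, spatial
   adjacency at a 0.4 chord-distance threshold, sign-homogeneous
   cluster formation, max-cluster-mass sign-flip permutation inference,
   Benjamini–Hochberg FDR for ROI-level maps, and one-sample Cohen's
   $d = t/\sqrt{N}$.

Because the participant recordings such an analysis is normally applied
to are not shippable, the package includes a first-class synthetic-cohort
generator whose ground truth (the latent arousal trajectory and every
channel/band coupling coefficient) is retained, so each stage's recovery
behaviour is testable end to end.

## The synthetic cohort: what it emulates

The generator produces four linked data sets from one latent process:

- **Latent arousal**: low-pass-filtered Gaussian noise at 1 Hz
  (cutoff `1/smoothness_s`; default 40 s), standardized. The smoothness
  default matches the 40 s smoothing window used throughout the pipeline,
  giving lag-1 autocorrelation above 0.9 — the temporal scale at which
  arousal trajectories actually move.
- **Annotation raters**: affine-rescaled mixtures
  `fidelity * latent + (1 - fidelity) * private noise`, restandardized,
  mapped to the 0–250 scale (centre 125, 40 rating units per z unit) and
  clipped. Fidelity is a free parameter of the generator — the rater noise
  structure is not identifiable from published group statistics — and the
  default of 0.7 produces strongly synchronized cohorts.
- **Pupil traces**: `baseline + a·latent − b·luminance + drift + noise`
  at 60 Hz, with injected blinks (200–400 ms drops below 5% of baseline
  with 50 ms linear ramps), isolated spikes, and missing runs. The
  artifact-free trace and every artifact mask are kept as attributes.
- **EEG**: per channel, $1/f^{\chi}$ background noise (FFT-shaped,
  default $\chi = 1.2$, 12 µV) plus band-limited oscillations whose
  amplitude envelopes follow `amplitude * max(1 + beta * latent, floor)`
  sampled-and-held at 1 s. Oscillations are narrowband-filtered noise,
  not pure tones, so Welch band power has realistic chi-squared
  variance; the alpha oscillation is centred on a per-subject IAF drawn
  uniformly from 8.5–12.5 Hz.

One further generator component deserves emphasis: a slow lognormal
**envelope-noise** term (`exp(envelope_noise_sd * eta(t))`, `eta` a
30 s-scale unit-variance process, default SD 2) multiplies every
channel/band envelope. Without it, band power tracks the latent almost
perfectly and subject-level arousal–power correlations approach −0.9,
an order of magnitude stronger than anything seen in real recordings.
With it, a coupling of `beta = -0.3` produces subject-level correlations
of roughly −0.1 to −0.25 with a between-subject SD near 0.15 — the
regime in which the cluster-level inference actually operates in
practice, where published cluster-average correlations sit near −0.1.
This term stands in for vigilance drifts and other endogenous power
fluctuations unrelated to the stimulus.

What the generator does **not** emulate: volume conduction and realistic
head geometry (channels are statistically independent apart from the
shared latent), ocular/muscle artifacts in the EEG, rater response lag,
or non-stationary coupling. Passing tests therefore demonstrate that the
statistics recover what they claim from signals with realistic amplitude
structure and autocorrelation — not that the pipeline is robust to every
failure mode of real recordings.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| annotation scale | 0–250 | rating units | the continuous rating scale's printed bounds |
| pupil rate | 60 | Hz | eye-tracker rate |
| initial exclusion | 300 | samples (5 s) | luminance adaptation at movie onset |
| moving-median / median-filter window | 100 | samples | interpolation and noise suppression scale |
| de-blink threshold | 3 | SD of first differences | two-sided, computed once per trace |
| spike threshold | 5 | MAD from running median | robust, scale-free; the pipeline's own median machinery |
| missingness gate | 0.40 | fraction | subject exclusion, checked after every stage |
| smoothing window | 40 | s (σ = window/6) | matches the slow autonomic dynamics |
| EEG rate | 200 | Hz | at least 5× the highest analyzed frequency (40 Hz) |
| Welch window | 1.28 | s, Hann, 50% overlap | standard spectral estimate |
| IAF spectra | 2 s window zero-padded to 10 s | — | 0.1 Hz grid for peak detection |
| spectral fit range | 2–40 | Hz (1–40 for IAF) | both ranges honoured per operation as printed |
| max peaks / min height / width limits | 6 / 0.15 log₁₀ / 1–20 Hz | — | fixed-mode parametrization settings |
| bands | delta 1–4 (2–4 in ISC contexts), theta 4–7, low-IAF [IAF−1, IAF] | Hz | both delta conventions are exposed as presets |
| adjacency threshold | 0.4 | chord distance on the unit sphere | neighbourhood scale of a 10–20 montage |
| permutations | 1000 (ISC, contrast), 10000 (sensor clusters) | — | empirical-null resolution |

## Numerical and design choices

- **Edge handling**: median filters use reflected-edge padding; Gaussian
  kernels are truncated at the window and renormalized over available
  samples, keeping the filter linear and shift-equivariant away from
  edges. The paper-style "window = 100/40 points" statements leave edge
  policy open; these are this package's choices.
- **De-blinking threshold**: the 3 SD first-difference threshold is
  computed once, after spike removal and interpolation, not recomputed
  iteratively. Recomputing after each removal would shrink the SD and
  cascade; one pass is stable and sufficient on traces whose artifacts
  were interpolated first.
- **Order of operations**: the luminance regression runs on the
  *unsmoothed* 1 Hz pupil series; Gaussian smoothing follows it. The
  regressor (luminance) is itself unsmoothed.
- **Fisher aggregation**: perfectly correlated pairs are clipped to
  `1 - 1e-12` before `atanh`, with a warning; otherwise a single
  degenerate pair would dominate the mean.
- **Surrogate construction**: circular shifts are drawn independently
  per subject and permutation, uniformly in `[min_shift, T − min_shift]`
  (default minimum 10 s) so that no surrogate is a near-identity
  rotation. All subjects are shifted; shifting all-but-one is a
  statistically equivalent alternative. The ISC p-value is one-sided
  (synchronization hypotheses are directional) with the add-one
  correction, so `p >= 1/(n_perm + 1)` and p is never exactly zero.
- **Aperiodic fitting**: "fixed" mode (no knee). The robust line fit
  excludes bins more than 1 SD above the first-pass fit before
  refitting, making the slope estimate peak-resistant; peaks are then
  fitted largest-first on the residual, the aperiodic is refit on the
  peak-removed spectrum, and a final bounded joint refinement runs over
  all parameters (kept only if it reduces the residual).
- **IAF**: the grid argmax of the flattened spectrum inside 8–13 Hz,
  requiring the model to have found a peak there; subjects without an
  alpha peak fall back to the group-median IAF with a warning. The IAF
  fit uses the 1–40 Hz range while the main model uses 2–40 Hz — both
  ranges are used deliberately where each is specified.
- **Band edges**: integer-edged bands take bins with `lo <= f < hi`,
  the top band also taking `hi`, so the shared 4 Hz edge is never
  counted twice; the low-IAF band averages bins with fractional-overlap
  weights since its edges are rarely on the 1 Hz epoch grid.
- **Cluster inference**: clusters are connected components (deterministic
  channel-index order) of supra-threshold, sign-homogeneous channels;
  the cluster mass is the summed |t| (reported signed). The sign-flip
  null retains the maximum mass over *both* signs per permutation — the
  more conservative of the two possible two-tailed realizations. The
  paired rest-vs-movie contrast implements label permutation as sign
  flips of per-subject differences, which is equivalent for a paired
  design.
- **Zero-variance guards**: zero-variance subjects are excluded from
  group means with a warning; zero-variance channels and degenerate
  constant differences raise errors naming the offender rather than
  propagating NaN.

## Problem sizes

The default pipeline scale is 12 subjects, 32 channels, 600 s of movie
and 120 s of rest at 200 Hz, with 1000 permutations per engine — chosen
so a complete run with every stage finishes in about two minutes on one
core while leaving all statistical behaviour intact. The full published
cohort scale (25 subjects with EEG, 35/30 for annotations/pupil, 64
channels, 1200 s, 10000 permutations) is reachable purely through
`pipeline_config()`. The test suite exercises permutation calibration at
300 null replicates and recovery power at 100 replicates, at the
correlation-map level where the spatial engine's behaviour is fully
determined by the per-subject map distribution.

## Known limitations

- Sensor adjacency uses an idealized spherical 10–20 montage, not
  digitized positions; cluster extents on real caps will differ in
  detail.
- The parametric cross-modal p-value ignores autocorrelation; use
  `method = "circular_shift"` for an honest null on smooth trajectories.
- ISC topographies are descriptive (no thresholding), mirroring standard
  practice for envelope ISC maps.
- Source localization is out of scope; ROI-level statistics
  (one-sample t, FDR, Cohen's d) are provided generically for any
  parcel-by-subject correlation table.
- The annotation generator's fidelity parameter is a modelling choice,
  not an estimate: nothing in published group statistics identifies the
  rater noise structure.
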