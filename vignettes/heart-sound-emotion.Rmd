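---
title: "Emotion recognition from heart sounds: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emotion recognition from heart sounds: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgemotion)
```

## The problem

Affective state modulates autonomic control of the heart. Heart-rate
variability (HRV) computed from ECG R-peak intervals is a standard input to
emotion classifiers, but ECG electrodes require skin contact. A
phonocardiogram (PCG) — the acoustic recording of the first and second heart
sounds S1 and S2 — can be collected with a wearable microphone and carries
the same beat-to-beat timing information, plus one quantity ECG cannot see:
the split of each cardiac cycle into systole (S1 onset to S2 onset) and
diastole (S2 onset to the next S1 onset).

`pcgemotion` implements a complete pipeline around two heart-sound
indicators:

* **HS HRV** — the beat-interval series from successive S1 midpoints.
  Because S1 is an extended wave packet rather than a sharp peak, beats are
  located at the midpoint of the S1 event: with onsets `thb` and offsets
  `tha` interleaved as S1, S2, S1, S2, … (length `2N` for `N` cycles),

  `S_M(i) = thb(2i-1) + (tha(2i-1) - thb(2i-1)) / 2`, and
  `RR_i = S_M(i+1) - S_M(i)` for `i = 1 … N-1`.

* **HS DSV** — the diastole-to-systole duration-ratio series,

  `DS_i = (thb(2i+1) - thb(2i)) / (thb(2i) - thb(2i-1))`,

  i.e. diastole of cycle `i` over its systole, also of length `N-1`. At
  rest `DS > 1` (diastole exceeds systole), which is also how the
  segmenter disambiguates S1 from S2. Whether diastole should be measured
  from the S2 *offset* instead of its onset is genuinely open; the onset
  reading keeps both durations on the same (onset-based) clock and makes
  the ratio a pure function of the onset array `thb`.

Each series is reduced to a named feature block and classified on three
axes of Russell's circumplex: valence (low = sad, angry), arousal (low =
relaxed, sad), and the four raw emotions.

## Segmentation

The segmenter (`segment_pcg()`) operationalizes a template/threshold
scheme on the normalized Shannon energy envelope
`-u^2 log u^2` (`u` the amplitude-normalized signal), which emphasises
mid-intensity lobes against both the noise floor and isolated spikes:

1. peak picking above an adaptive threshold (`peak_frac` = 0.25 of the
   99.5th envelope percentile) with a 0.10 s refractory separation;
2. boundary refinement at the 10 %-of-peak crossing of a 6 ms moving-RMS
   amplitude envelope (the Shannon envelope itself dips where the signal
   touches the normalization maximum, so boundaries come from the
   amplitude envelope);
3. S1/S2 labeling by interval alternation — the shorter of the two
   alternating onset gaps is the systole — with a median consistency check
   and a duration-constrained repair pass (S1 in 0.04–0.25 s, S2 in
   0.03–0.20 s);
4. incomplete leading/trailing cycles are dropped; fewer than three
   complete cycles is an error, and any candidate set that cannot be
   repaired into a valid interleaved array raises rather than returning a
   silently inconsistent segmentation.

Boundaries are a *convention*, not an observable: no operational definition
of an event's "start" exists upstream, so the package defines both the
generator's annotations and the detector's refinement rule at the 10 %
amplitude point. The two are therefore mutually consistent by construction,
and segmentation accuracy against ground truth measures detector noise, not
disagreement between two arbitrary conventions.

Preprocessing is a zero-phase order-4 Butterworth low-pass at 200 Hz
(`lowpass()`); the cutoff retains S1/S2 energy (dominantly below ~150 Hz)
and is configurable. The quality gate (`preselect()`) rejects recordings
with (a) no dominant envelope periodicity at lags 0.3–1.5 s, (b) more than
25 % of spectral power above 400 Hz (speech/laughter-band interference), or
(c) runs of samples pinned at the amplitude extreme (clipping). These are
invented operationalizations of a verbal screening rule; all thresholds
live in the configuration.

## Features

Per interval series (`feature_block()`):

| group | RR-kind | DS-kind |
|---|---|---|
| time domain | mean, sdnn, rmssd, pnn50, cv, median, mad (7) | same minus pnn50 (6) |
| frequency domain | vlf, lf, hf, lf_hf, lf_nu, hf_nu (6) | lf, hf, lf_hf (3) |
| lagged Poincaré | sd1, sd2, sd12 for M = 1…22 (66) | same (66) |
| total | 79 | 75 |

The combined heart-sound block prefixes and concatenates both: 154
features. The exact feature inventories used in prior emotion heart-sound
work are not publicly documented; this registry is a reconstruction that
closes the 79/75/154 block sizes reported for this family of methods using
only standard, documented HRV statistics plus the lagged-Poincaré family,
with the lag sweep `M = 1…22` both spanning the range over which the SD12
contrast between arousal levels is visible and closing the dimension
budget.

The lagged-Poincaré dispersions are implemented exactly as defined,
including the `1/(N-M)` normalization (not `N-M-1`) and the full-series
mean in SD2:

`SD1 = sqrt( mean_i[(x_i - x_{i+M})^2 / 2] )`,
`SD2 = sqrt( mean_i[(x_i + x_{i+M} - 2 x̄)^2 / 2] )`, `SD12 = SD1/SD2`.

Everywhere else the sample SD uses `N-1`. When `SD2 = 0` (constant
series), `SD12` is recorded as missing and median-imputed at matrix
assembly (`build_matrix()` logs an imputation mask) — this keeps
infinities out of the classifier while preserving the column.

Spectral features use a hand-implemented classic Lomb–Scargle periodogram,
since beat intervals are unevenly sampled in time: RR series live on the
cumulative beat-time axis with the standard short-term bands (VLF
0.003–0.04, LF 0.04–0.15, HF 0.15–0.4 Hz); DS series have no natural time
axis and are treated as evenly indexed by cycle, reusing the LF/HF band
edges in cycles/beat. Band ratios with zero denominators are recorded as
missing, like `SD12`.

## Classification

`cv_fitness()` scores a feature mask by pooled accuracy of an RBF-kernel
support-vector classifier over stratified 5-fold cross-validation.
Standardization parameters are computed on each training fold only — the
suite contains an explicit leakage test. The SVM is trained by sequential
minimal optimisation with first-order maximal-violating-pair working-set
selection (deterministic, no RNG); one-vs-one voting handles the
four-class task; `class_weight = "balanced"` scales each class's box
constraint by `n/(k·n_c)` to counter the 43-vs-14 imbalance. The
implementation reproduces a reference SVM's predictions exactly on frozen
oracle datasets (see `test-classify.R`).

Feature selection wraps that fitness in a binary-mask genetic algorithm
(`ga_select()`): population 30, 50 generations, tournament size 3, uniform
crossover 0.7, per-bit mutation `1/D`, elitism 1 — conventional wrapper
defaults, all configurable; the elitist best-fitness trace is
non-decreasing by construction. Selection is repeated 30 times
(seeds `base+0 … base+29`); runs ranking in the top 20 % by best fitness
(`ceil(0.2·30) = 6`) are retained, each feature's *weight* is its selection
frequency among retained runs, and the consensus subset keeps features
with weight ≥ 0.5 (majority; the source never defines the weight formula —
this is the package's definition). An empty consensus falls back to the
single best run's mask. Finally `tune_cg()` grid-searches
`log2 c ∈ [-5, 15]`, `log2 g ∈ [-15, 3]` in steps of 2 (whether the
original parameter search was evolutionary or grid is unstated; the grid
is exhaustive and deterministic, with ties resolving to the first grid
point).

## The synthetic world

No emotion heart-sound corpus is publicly deposited, so `make_dataset()`
generates one with known ground truth. Its defaults are a *stated world*,
fixed once:

* RR intervals: stationary AR(1) — the simplest process with a tunable
  lag structure, so lagged-Poincaré features vary with `M`. Per-emotion
  parameters encode the qualitative contrasts reported for emotional
  cardiac dynamics: high-arousal states (happy, angry) beat faster with
  denser, less variable interval clouds — lower SDNN, higher lag-1
  correlation, hence lower SD12 across lags — while low-arousal states
  (relaxed, sad) are slower, more variable, less correlated. Within each
  arousal level, valence separates through rate and DS level. Defaults
  (relaxed / happy / sad / angry): mean RR 0.92 / 0.75 / 0.86 / 0.68 s,
  SDNN 60 / 35 / 50 / 25 ms, lag-1 correlation 0.30 / 0.65 / 0.40 / 0.75,
  mean DS 1.80 / 1.50 / 1.70 / 1.35, DS CV 8 / 5 / 10 / 4 %. These are
  physiologically plausible resting figures for young adults, not
  source-derived measurements (none are published).
* DS ratios: i.i.d. lognormal with the profile's mean and CV, truncated so
  systole stays ≥ 0.15 s; RR is truncated above 0.25 s. The truncations
  prevent degenerate packet overlap and essentially never trigger at the
  default parameters.
* Waveform: each cycle places an S1 packet (Gaussian-windowed 80 Hz burst,
  0.12 s) at the cycle start and an S2 packet (120 Hz, 0.09 s, amplitude
  0.8) after the systole implied by `rr/(1+ds)`; the Gaussian sigma puts
  the 10 %-amplitude points exactly at the annotated boundaries, and
  packets are truncated there so the noise-free waveform is exactly silent
  between events. White noise is added at a requested SNR (default 20 dB).
  Textbook packet frequencies/durations; corpus layout (96 segments,
  43/21/18/14 across relaxed/happy/sad/angry, 150 s segments mirroring
  300-s recordings split in half, 16 subjects) mirrors a published emotion
  heart-sound corpus layout.

What the generator does *not* emulate: murmurs, S3/S4, respiratory
modulation of amplitude and rate, sensor coupling drift, inter-subject
timbre differences, or any physiologic coupling between RR and DS beyond
their per-emotion levels. A green end-to-end test therefore establishes
that the pipeline *recovers planted dynamics from rendered audio* — a
parameter-recovery result, not a reproduction of human-subject accuracies.
One visible consequence: in this stated world the arousal axis separates
more strongly than valence (the arousal contrast is what the profile
invariants encode), so the ordering reported for human data — valence
easiest — is not reproduced and is not asserted; the acceptance suite
asserts the hard
recovery criteria instead (four-class accuracy ≥ 0.80; the combined
154-feature block within 0.05 of the best single block).

## Numerical and testing notes

* All randomness flows through explicit integer seeds (`with_seed`
  internally); re-running any stage with identical inputs and seeds is
  byte-identical. The SMO solver and the GA's tie-breaks are
  deterministic.
* Butterworth design (bilinear transform with prewarping, DC gain pinned
  to exactly 1) and forward–backward filtering with steady-state edge
  initialization were validated against an independent reference
  implementation to ~1e-14 during development; the shipped tests assert
  the analytic `|H|^2` magnitude response instead, keeping the oracle
  independent.
* Spectra are computed on zero-padded, highly composite lengths — a
  mixed-radix FFT degrades to minutes on prime-length recordings.
* Test budgets: the acceptance corpus uses 60-s segments (not 150 s) and
  reduced GA budgets (population 16–20, 8–15 generations vs the 30/50
  production defaults); thresholds are never adjusted, only problem sizes.
* Known limitations: the segmenter assumes resting sinus rhythm with
  `DS > 1` and will mislabel S1/S2 under extreme tachycardia; boundary
  accuracy inherits the envelope-threshold convention; the preselection
  thresholds were chosen on synthetic interference and will need
  re-screening on real wearable data.
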