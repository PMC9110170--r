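---
title: "mindfuse: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mindfuse: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

mindfuse scores ten binary mental-health indicators (an SCL-90-style
checklist: somatization, obsessive-compulsive symptoms, interpersonal
sensitivity, depression, anxiety, hostility, dreadness, crankiness,
psychopathy, other) from three behavioural streams per subject:

* **face** — 68 facial landmarks per frame (OpenPose output convention),
* **gait** — 18 body joints per frame,
* **voice** — mono speech.

The pipeline is feature-layer fusion: each modality is reduced to a
channels-by-statistics matrix, the three matrices are concatenated after
being scaled by softmax attention weights, and the flattened fused feature
goes to a bank of ten independent soft-margin SVMs with a Gaussian kernel
$K(x,z) = \exp(-\lVert x-z\rVert^2 / 2\sigma^2)$ (binary relevance: one
classifier per indicator, positive = screens positive).

### Keypoint features

Streams are validated (68/18 points per frame, confidences in $[0,1]$),
repaired (points below a confidence threshold of 0.1 are linearly
interpolated along time, edge gaps held at the nearest valid value) and cut
into fixed windows: 30 s for face, 8 s for gait; a trailing partial window
of at least half the target duration is kept, shorter remainders are
dropped. Each keypoint then becomes one scalar channel: the Euclidean
distance of the point from its own within-window mean position. This choice
(rather than per-axis series) is translation-invariant, insensitive to where
the subject stands in the frame, and yields exactly one channel per
landmark, so the fused feature has $68+18+17 = 103$ channel rows. The raw
x/y series are retained per channel solely for the axis-correlation
statistic.

### Voice features

Audio is Wiener-denoised (local mean/variance adaptive filter, window 11
samples, noise power = mean local variance), cut into 1 s segments (trailing
partial of at least 0.5 s kept), and analysed in short-time frames of 25 ms
at a 10 ms hop. Per frame, 17 descriptors:

| descriptor | path | notes |
|---|---|---|
| `E` | raw frame | short-time energy $\sum_n y_i^2(n)$, no window |
| `PF` | 40 ms Hamming window | cepstral pitch, band 50–500 Hz; 0 = unvoiced |
| `For1..For3` | pre-emphasis 0.97 + Hamming | LPC-root formants, order $2 + sr/1000$ |
| `mfcc1..12` | pre-emphasis 0.97 + Hamming | 512-point FFT power spectrum, 26 triangular Mel filters, log (floor $10^{-10}$), orthonormal DCT-II, coefficients 1–12 (0 dropped) |

Numerical details that matter:

* **Pitch.** The real cepstrum is the inverse FFT of the base-10
  log-magnitude spectrum, clamped to 4 decades below each frame's spectral
  peak so near-zero bins (window sidelobes) cannot dominate. Beyond
  quefrency zero this is amplitude- and polarity-invariant. A frame is
  voiced if the cepstral peak in the quefrency band reaches the prominence
  threshold 0.08 — on this scale voiced synthetic speech peaks around
  0.15–0.25 and white noise stays below 0.05. The cepstral test needs at
  least two harmonics, so a second route covers degenerate single-line
  spectra: if the strongest spectral peak lies in the pitch band and carries
  at least half the frame power, the frame is periodic by inspection and the
  pitch is the (parabolically interpolated) peak frequency. A pure sine is
  the canonical case.
* **Pitch window.** Searching down to 50 Hz requires two periods = 40 ms,
  longer than the 25 ms analysis frame. The pitch path therefore uses a
  dedicated 40 ms window at the same hop and start positions (zero-padded at
  the segment tail), so all 17 channels stay frame-aligned.
* **Formants.** Levinson–Durbin autocorrelation LPC; polynomial roots with
  positive imaginary part qualify as formants if their bandwidth is below
  400 Hz and their frequency is in $[90, sr/2 - 50]$ Hz; the lowest three
  are returned ascending, zero-filled when fewer qualify. When aggregating
  across frames (recovery tests, summaries) the **median** is used: an
  order-18 LPC fit occasionally places a spurious narrow-bandwidth root
  between true formants, which corrupts a mean but not a median.
* **Unvoiced frames** are masked invalid on the pitch channel only. A fully
  unvoiced segment leaves the pitch channel without valid points; the
  statistics stage encodes that row as zeros with a warning instead of
  failing, keeping the matrix shape.

### Time-domain statistics

Nine statistics are available per channel — sum, mean, min, max, variance,
standard deviation, skewness, kurtosis, and the x/y axis correlation — with
sample ($n-1$) variance, adjusted Fisher–Pearson skewness, excess kurtosis,
and the conventions: zero-variance series have skewness = kurtosis = 0;
axis correlation is 0 when either axis is constant or the channel has no
axis pair (voice). The **default set is the four-statistic subset
{mean, std, skewness, kurtosis}**, which makes the matrices 68×4, 17×4 and
18×4 and the fused feature 103×4 (a 412-vector when flattened row-major).
All nine remain selectable via `stats.set`; the four-statistic default is
what fixes the fused size at 103×4.

### Attention fusion

Each modality is summarized by a descriptor: the column-wise mean of its
feature matrix (one value per statistic). The descriptors are the keys; the
query is their element-wise mean. Similarity is configurable — dot product,
cosine (default), bilinear $k^\top W q$ (identity $W$ unless supplied), or
scaled dot $\langle q,k\rangle/\sqrt{d}$ — and the weights are the softmax
(max-subtracted for overflow safety, temperature exposed, default 1) of the
three similarities. Each modality block is multiplied by its weight and the
blocks are stacked in the fixed row order face, gait, voice. Weights are
computed **per sample**, from the sample's own descriptors; a global
variant can be had by averaging weights across a training set.

Two deliberate choices:

* **Cosine as default.** It is bounded and scale-free, which matters because
  the three modalities live in different units (pixels vs Hz vs unitless).
* **No descriptor z-scaling by default.** Z-scaling descriptors (fit on
  training data) centres them near zero; the cosine between the near-zero
  query and each key then swings wildly from sample to sample, and the
  resulting weight variation acts as multiplicative noise on every feature.
  In our evaluation harness this demoted fused accuracy from the plain
  concatenation level to well below it, so raw descriptors are the default
  and z-scaling is opt-in (`attention_config(scale_descriptors = TRUE)`).

For ablation conditions with fewer than three modalities, attention is
undefined under the three-way softmax; dual conditions use a two-way softmax
when attention is explicitly requested and plain concatenation otherwise.

### Classification and evaluation

Ten soft-margin Gaussian-kernel SVMs (penalty $C = 1$) are trained on the
standardized flattened features via a deterministic SMO solver
(first index by scan order, partner by maximal error difference), so
converged predictions do not depend on sample order. The default kernel
width follows the scale rule $\sigma^2 = d\,\mathrm{Var}(X)/2$ (equivalently
kernel coefficient $1/(d\,\mathrm{Var})$). A `degree` setting is accepted
for configuration fidelity and ignored — it parameterizes a polynomial
kernel, not a Gaussian one.

Evaluation is stratified k-fold cross-validation per indicator (default
$k = 5$, seed 42; a single counter across the shuffled classes keeps folds
balanced and makes $k = n$ exact leave-one-out). Within each fold, anything
fitted (feature standardization, kernel width, optional descriptor scalers)
uses the training part only. Out-of-fold predictions are pooled and
summarized as accuracy, precision, recall and F1, with zero-denominator
conventions (0, not NaN) so degenerate folds stay defined. "Overall"
numbers are macro-averages over the ten indicators. The ablation grid runs
F, V, G, F+V, F+G, V+G, F+V+G (plain) and F+V+G with attention.

## The synthetic cohort

No subject data ships with the package — recordings in this domain are
sensitive and reference datasets are typically private — so every stage is
exercised against a generator that emulates the two stream families:

* **Voice** is a source–filter synthesis: a glottal pulse train at $f_0$
  through a cascade of two-pole resonators (formants, 80 Hz bandwidths),
  plus white noise, peak-normalized to 0.9, then a spectral-tilt filter and
  a gain. Default protocol: three 1 s segments at 16 kHz per subject.
* **Keypoints** oscillate sinusoidally about a canonical base pose with
  per-point phase and direction, plus Gaussian pixel jitter; confidences are
  drawn in $[0.6, 1]$. Default protocol: one 30 s face stream and one 8 s
  gait stream at 25 fps.

Labels are independent Bernoulli draws per indicator (default prevalence
0.5). Effects are standardized mean shifts of generative parameters: for
each positive indicator, face shifts the motion amplitude of six owned
landmarks, gait shifts an owned joint pair (indicator 10 shifts the global
gait amplitude), and voice shifts one of six knobs
($f_0$, For1, For2, For3, gain, tilt; indicators 7–10 reuse the first four
with negative sign). Between-subject parameter variation defines the unit of
"standardized": e.g. $f_0 \sim N(120, 10)$ Hz, so a voice effect of 2 on
indicator 1 shifts $f_0$ by 20 Hz. The manifest records the spec and seed,
and all randomness flows from one master seed through derived per-subject
streams.

What the generator does **not** emulate: photorealistic appearance,
articulated body kinematics, coarticulated natural speech, label
comorbidity (a shared latent factor is a documented possible extension, off
by default), session effects, or sensor dropout beyond confidence jitter. A
green test therefore establishes that the pipeline recovers planted
statistical structure under its own stated noise model — not clinical
validity on real recordings.

### Acceptance worlds

The acceptance tests fix their worlds up front:

* *Separability* (criterion: fused 5-fold overall accuracy at least 0.95)
  uses uniform effects of 5 — the "cluster shift 5 sd" regime — at
  $n = 200$.
* *Null calibration* uses all-zero effects at $n = 200$; every indicator
  must sit within $0.5 \pm 0.1$.
* *Ablation ordering* uses **complementary planting**: face carries
  indicators 1–4 (effect 2), voice 5–7 (effect 3), gait 8–10 (effect 2).
  Real behavioural markers are modality-specific in exactly this way, and it
  places the generator in the regime fusion experiments are about: no single
  modality can score all ten indicators, so the fused condition should beat
  the best single modality. Voice gets the largest effect because its
  per-indicator signal lives in fewer channels. The criterion asks the
  attention-fused condition to win in at least 8 of 10 seeded replicates.
* *Chance* under permuted labels and the one-modality ordering check
  (signal only in face implies F ≥ V and F ≥ G) use the same machinery.

## Known limitations

* The SMO solver targets desk-scale problems (hundreds of samples); no
  shrinking or working-set caching.
* Formant estimation assumes adult-range vocal tracts via its bandwidth and
  frequency gates; heavily nasalized or high-pitched input can merge
  harmonics and formants (a known LPC limitation).
* Pitch is reported per frame without octave-error tracking across frames.
* The keypoint displacement channel discards motion direction; periodicity
  of gait is captured only through the time-domain statistics of the
  magnitude series.
* WAV I/O supports mono PCM-16 and float-32 only; multichannel input is
  rejected with guidance to downmix.
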