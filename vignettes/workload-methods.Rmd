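---
title: "An EEG workload neurometric: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An EEG workload neurometric: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegworkload)
```

## The problem and the model

Sustained mental workload shifts the scalp EEG in a well-replicated way:
theta-band power over frontal midline sites rises and alpha-band power
over parietal sites falls. `eegworkload` turns that physiology into a
per-subject workload index. A short calibration recording containing a
known low-workload segment (class 0) and a known high-workload segment
(class 1) is used to fit a linear discriminant on spectral features,

$$y(t) = \sum_i w_i\, f_i(t) + b,$$

where $f_i(t)$ are (log) power spectral density values at specific
(channel, frequency-bin) pairs of a 2-s epoch ending near time $t$. The
least-squares fit of the 0/1 class label on the features gives the same
discriminant direction as two-class LDA up to an affine scale, so the
trained output tends to 0 in easy and 1 in hard conditions. New data are
scored with the frozen weights, and an 8-s moving average of $y(t)$
yields the workload index `WL_SCORE` at 8-s time resolution — a
compromise between temporal resolution and variance of the estimate.

Scores are deliberately **not clipped** to $[0, 1]$: the bracket is a
tendency of the trained scale, not a constraint, and clipping before the
moving average would bias window means toward the interior.

## Band definitions and the Individual Alpha Frequency

Alpha peak frequency varies between people, so fixed band edges blur the
effect the discriminant feeds on. All bands are therefore anchored to
the Individual Alpha Frequency (IAF), estimated as the frequency of the
maximum of the epoch- and parietal-averaged PSD of an eyes-closed
baseline, searched in 7–13 Hz. Theta is $[IAF-6, IAF-2]$ Hz over AF3,
AF4, F3, Fz, F4; alpha is $[IAF-2, IAF+2]$ Hz over P3, P7, Pz, P4, P8,
POz; both bands include their endpoints and share the $IAF-2$ bin. With
2-s epochs (0.5 Hz bins) this gives 17 bins per channel, 187 (channel,
bin) pairs over the 11 analysis channels, and 99 selectable features:
45 frontal-theta and 54 parietal-alpha. Endpoint inclusiveness is the
only reading consistent with those counts. If no spectral maximum lies
strictly inside the search range the estimate falls back to 10 Hz — the
population-typical peak — with a warning, so batch runs surface the
degenerate case rather than silently miscalibrating.

Features enter the classifier as $\log_{10}$ PSD. Band power is heavily
right-skewed across epochs; the log stabilizes the variance and makes
the linear model's residual assumptions far more plausible. A `linear`
option is kept for sensitivity checks.

## Preprocessing decisions

**Filtering.** The 1–30 Hz band-pass is implemented as a cascade of a
fourth-order high-pass and a fourth-order low-pass Butterworth section,
each applied forward–backward (`signal::filtfilt`). Zero-phase
application matters because epochs are aligned to annotated task
segments; a causal filter would delay the spectral content relative to
the labels. The cascade form is also numerically safer than a single
eighth-order band-pass with an edge at 1/128 of the sampling rate.

**Blink removal.** Blinks dominate the forehead channel (FPz) and leak
into frontal — and weakly into parietal — channels, contaminating
exactly the theta band the metric relies on. Intervals are detected on a
6 Hz low-passed FPz envelope by an amplitude criterion (50 μV) or a
derivative criterion (1000 μV/s); detected runs are padded by 0.15 s and
merged. Within each interval only, every other channel is regressed on
the reference and the fitted component $\beta\,(\mathrm{FPz} -
\overline{\mathrm{FPz}})$ is subtracted, the baseline being the
recording-wide reference mean (≈0 after the high-pass) so the
correction does not step the channel mean inside the interval. Outside
the intervals samples are untouched: the correction loses no data. The
derivative threshold sits an order of magnitude above the envelope
derivative of ordinary background EEG (~130 μV/s RMS at 10 μV RMS
input) and well below a blink's (~2000 μV/s). The remover is a
self-contained detection-plus-regression design; FPz itself never
enters the feature set.

**Epoching and artifact rejection.** 2-s epochs shifted by 0.125 s give
a dense score series while keeping each epoch short enough for
quasi-stationarity. (With those numbers consecutive epochs overlap by
1.875 s.) Three per-channel criteria flag an epoch: maximum absolute
amplitude above 100 μV; absolute slope of the ordinary least-squares
linear fit against time above 10 μV/s (the fit is computed on the raw
samples — no envelope resampling); and maximum absolute
sample-to-sample difference above 25 μV. Any failing non-reference
channel flags the whole epoch — the conservative reading, since a
contaminated channel corrupts the joint feature vector. Criteria are
evaluated on the filtered, blink-corrected signal, matching the
processing order; flags accumulate as reason codes and the operation is
idempotent. Note that crafted inputs can legitimately trip several
criteria at once: a one-sample 150 μV spike exceeds both the amplitude
and the step bound, and a 30 μV mid-epoch step also tilts the
least-squares slope to 22.5 μV/s.

**PSD.** One Hanning-windowed periodogram per epoch and channel — the
window spans the whole epoch, so the bin spacing is exactly
1/epoch-length and no sub-window averaging (Welch) is done; sub-windows
would halve the frequency resolution the band arithmetic depends on.
The window is power-normalized ($2/(f_s \sum w^2)$, one-sided) so a
stationary sinusoid of amplitude $A$ integrates to $A^2/2$.

## The stepwise fit and its stopping rule

Candidates enter by the smallest partial-F $p$-value (entry threshold
0.05) and selected features are dropped again when their $p$ rises
above 0.10, never the one entered in the same step. Ties break toward
the lowest index in the canonical channel-major ordering, making the
trace deterministic. Training halts when (a) no candidate passes entry,
(b) the selection reaches a cap of 10 features, or (c) the mean squared
error on a held-out stratified validation split (25% of training
epochs, fixed split seed) has not improved for 2 consecutive steps, in
which case the selection reverts to the best validated step. The rule
is a configurable re-specification of an automatic-stopping idea whose
original form is proprietary; all three knobs live in
`stepwise_config()`. Final weights and bias are always the ordinary
least-squares solution on the *full* training set over the selected
features; with nothing selected the model is bias-only with $b$ equal
to the class-label mean. Identical features, labels and configuration
reproduce the identical model, down to the serialized JSON bytes.

On the default synthetic cohort the validation rule rarely fires before
the cap because the injected effects are strong and spatially
distributed, so models typically carry the full 10 features; on real
data with weaker, more localized effects the entry threshold and
validation rule bind earlier and models are much sparser.

## The workload series

Epoch scores live on the 0.125-s grid internally; the public series
averages them over consecutive 8-s windows (one output per window).
Each output records its **coverage** — retained epochs divided by the
64 expected per window — and outputs below 25% coverage are reported
missing: a window containing a single surviving epoch is not an 8-s
average and must not pretend to be one. Condition aggregation uses only
windows lying entirely inside one annotated segment. Event analysis
averages the index over a fixed window from each event onset (20 s for
a car encounter, 10 s for a pedestrian crossing) and compares it with a
matched window in the previous lap's segment of the same hour and road
at the same offset from segment start — the "same circuit position"
notion available without telemetry; the event's position key pairs the
two windows in the output.

## Evaluation battery

AUC is computed by the rank-sum identity, $P(s_1 > s_0) + \tfrac12
P(\text{tie})$, and validated in the tests against brute-force pair
counting. The chance reference is a shuffled-label baseline: the AUC
distribution under random label permutations, centered at 0.5 no matter
how separable the true scores are. Paired comparisons use the two-sided
Wilcoxon signed-rank test (zero differences dropped; exact null for
n ≤ 25 without ties, normal approximation with continuity correction
otherwise) and the Friedman rank test for the 2 × 2 condition table; a
fully tied table short-circuits to statistic 0, $p = 1$, where the
generic tie correction is 0/0. Families of $p$-values are adjusted by
Benjamini–Hochberg; the family is whatever is passed in one call, as in
the three-comparison classification analysis. NASA-TLX is scored as the
ratings weighted by pairwise-comparison win counts over 15, the
"Performance" scale used exactly as rated.

## The synthetic generator

The generator emulates the statistical structure the neurometric
assumes, with full ground truth: band-limited (1–30 Hz) $1/f$
background on every channel (exponent 1, 10 μV RMS — peaks stay well
under the 100 μV rejection bound so clean data survive rejection);
an alpha source of band-limited filtered noise (2 Hz wide) at the
subject's IAF on parietal channels, doubled during the eyes-closed
baseline; a theta source centered at IAF−4 Hz on frontal channels;
blink transients (sin² bumps, 200 μV, 0.3 s, ~10/min) propagated from
FPz with coefficients decaying toward parietal sites; and sporadic
200 μV transients on random non-reference channels. Sources are
filtered noise rather than sinusoids so every ROI bin is populated, as
in real EEG, and each channel draws an independent source realization.

Condition effects multiply source *amplitude* — Hard road: theta ×1.5,
alpha ×0.7; Rush hour pushes both effects further (theta ×1.2, alpha
÷1.2) — hence band *power* moves by the squared gains, which is what
the oracle band-power checks assert. Events add a further ×1.4 theta
gain inside their windows. The default session follows the study-like
protocol: 60 s eyes closed, then per traffic hour three laps of an
Easy and a Hard 40-s segment, with a pedestrian and a car event acted
in the third lap. A single master seed expands into per-component
substreams so one component can vary while the rest stay fixed.

What the generator does **not** emulate — volume-conducted correlation
between channels, non-stationary drifts, muscle artifacts with spectral
overlap, saccades, alpha/theta reactivity differences across subjects —
bounds what passing tests show: they demonstrate that the pipeline
recovers the structure it assumes, not that real driving EEG satisfies
those assumptions.

## Problem sizes and numerical choices

The validation cohort is 16 simulated subjects (IAFs drawn on the
0.5 Hz grid in 9–11 Hz), each a 540-s session: enough for ~300
calibration epochs per class and 16 labeled 8-s test windows per
subject, which puts the per-subject test AUC comfortably above 0.9
under the default effects while keeping a full cohort run in the
low minutes. The shuffled baseline uses 100 permutations per subject;
type-I-error checks use 1000 null replicates. PSD values are floored at
10⁻¹⁵ μV²/Hz before the log so all-zero epochs stay finite; EDF output
quantizes to 16 bits over each channel's observed range; band-edge
matching tolerates a quarter-bin of floating-point slack. Degenerate
inputs fail loudly and specifically: missing montage channels, bands
below the high-pass cutoff, single-class training sets, unmatched event
positions and malformed annotation rows all name the offending item.

## Known limitations

The blink remover is a linear, interval-local approximation: a blink
overlapping a genuine theta burst will remove the correlated part of
both. IAF is estimated once per session; drift within very long
sessions is not tracked. The stepwise selection inherits the usual
caveats of stepwise inference — its $p$-values are selection-biased and
are used only as ordering/stopping devices, never reported as tests.
Cross-subject transfer, regularized variants and online retraining are
out of scope.
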