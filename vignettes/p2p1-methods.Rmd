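---
title: "Methods: automated P2/P1 subpeak-ratio monitoring on ICP signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated P2/P1 subpeak-ratio monitoring on ICP signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(icpratio)
```

## The problem

A single cardiac cycle imprints a pulse on the intracranial-pressure (ICP)
signal of a monitored intensive-care patient. When the cerebrospinal system
is compliant, the pulse usually shows up to three subpeaks of decreasing
amplitude — P1 (percussion), P2 (tidal), P3 (dicrotic). As compliance
degrades, P2 rises relative to P1, so the quotient of their relative
amplitudes, the **P2/P1 ratio**, works as a bedside compliance indicator:
values above 1 are read as impaired compliance. The ratio is not always
defined — artifacts and morphologies with a missing subpeak make many beats
non-calculable — so the output of any automatic estimator is an
intermittent, noisy per-beat series that must be screened and smoothed
before a clinician sees it.

`icpratio` implements the full chain from a raw single-channel 100 Hz ICP
record to the displayed ratio series, in five stages:

1. **Preprocessing** — band-pass filtering, multiscale pulse-onset
   detection, beat segmentation, normalization to a common 180-sample
   frame;
2. **Pulse selection** — a binary sequence classifier that discards beats
   without a calculable ratio;
3. **Candidate detection** — curvature-based concave-landmark candidates;
4. **Subpeak designation** — a network regressing a per-sample
   subpeak-proximity score, read either at the curvature candidates or at
   its own local maxima, giving P1, P2 and the ratio;
5. **Postprocessing** — causal sliding-window smoothing with outlier
   rejection and gap awareness.

Because clinical ICP recordings are confidential, the package also ships a
first-class synthetic generator (`generate_record()`,
`simulate_pulse_dataset()`) that emulates the signal class and provides
exact ground truth; every performance claim in the test suite is measured
on that synthetic data, never on patient data.

## Synthetic data model

A beat is a sum of up to three Gaussian bumps on a flat baseline,
parameterized by per-subpeak amplitude, centre (fraction of beat duration)
and width (`pulse_template()`). Records concatenate beats at a configurable
heart rate with per-beat period jitter, then add

* a respiratory sinusoid (default 0.25 Hz — a typical ventilated breathing
  rate, and safely below the 0.3 Hz analysis band edge),
* a slow baseline drift (white noise low-passed below 0.1 Hz, again outside
  the analysis band, so preprocessing can be validated against it), and
* white broadband noise.

The target P2/P1 trajectory is *realized*, not merely copied into
parameters: the second-subpeak amplitude is solved per beat so that the
rendered, min–max-normalized waveform attains the requested ratio at its
apexes. Ground-truth subpeak positions are re-derived from the rendered
waveform's local maxima rather than from the template centres, because
overlapping Gaussians shift the apexes: the labels must match what a
perfect detector could recover.

Two generator choices deserve comment.

* **Default record morphology.** The record template uses widths
  (0.06, 0.06, 0.11) of the beat duration, the third subpeak widest: the
  dicrotic wave decays into diastole, which gives the inter-beat trough a
  V shape (a flat inter-beat valley would leave the onset ill-defined).
  Apexes for the default 180-sample rendering sit near samples 41, 81
  and 121. The per-pulse dataset generator draws from the same family
  (sharp P1/P2, wide P3), so classifiers trained on dataset pulses
  transfer to record-extracted pulses.
* **Resolvability of labeled subpeaks.** In the per-pulse dataset
  generator, P1/P2 widths are drawn in 0.04–0.07 of the beat
  duration (P3 in 0.08–0.12) and a Rayleigh-style guard re-draws beats whose rendered P1–P2 apex
  separation falls below ≈2.8 standard deviations. Two Gaussians closer
  than that merge into a single crest whose apexes no longer mark the
  component waves; a human annotator would not label such a beat as
  showing two distinct subpeaks (labeling in this problem is deliberately
  restrictive), and the curvature candidates would not coincide with the
  apexes. Non-calculable pulses mix missing-P1/missing-P2 renderings with
  artifact shapes (spikes, noise bursts, monotone decays).

What the generator does **not** emulate: Lundberg waves, sensor drift
physics, heart-rate variability structure beyond white period jitter,
baseline-dependent morphology changes, and the full diversity of clinical
artifact shapes. Passing tests on this data therefore demonstrates that the
algorithms are implemented correctly and can learn and track the intended
morphology class; they say nothing quantitative about patient data, whose
published operating figures (selection AUC ≈ 0.9 and related table values)
come from confidential recordings and are reproduced here only at the level
of their contingency arithmetic.

## Preprocessing

The band-pass filter is a fourth-order Butterworth design with edges 0.3
and 20 Hz, applied forward and backward. The zero-phase choice is an
interpretation (the reference description does not state phase handling):
appearance-time error is a headline metric, and a causal filter's group
delay would bias subpeak timing. Forward–backward filtering needs edge
handling; the implementation extends the record by odd reflection over
three periods of the lowest passed frequency, long enough for the 0.3 Hz
pole transients to die inside the padding. Records shorter than that
warm-up are rejected.

Onset detection is a bounded-scale multiscale trough detector (the
"modified Scholkmann" / AMPD family): for scales $k = 1..L$ a sample $i$
is marked when $x_i < x_{i-k}$ and $x_i < x_{i+k}$; the working scale
$\lambda$ maximizes the number of marked samples (ties resolve to the
smallest scale — the finest consistent scale, and deterministic), and
onsets are samples marked at *every* scale up to $\lambda$. The
characteristic duration is $L$ = 500 ms, intended as at least a quarter of
the beat period. Troughs are detected directly with minima comparisons
rather than running the peak form on a negated signal — equivalent and
clearer. The detector compares amplitudes only, so it is scale-invariant.

Segmentation takes `[onset_j, onset_{j+1})` and drops beats outside
0.25–2 s (30–240 bpm; the expected pulse rates are 60–80 bpm, so the gate
is permissive and only guards against missed or spurious onsets).
Normalization maps each beat to $[0,1]$ by min–max and resamples to 180
points with a piecewise cubic through all samples ("third-degree
polynomial interpolation" read as piecewise, since a single global cubic
cannot represent three subpeaks). Cubic interpolation can overshoot
slightly, so the min–max anchoring is re-applied after resampling; this
also makes normalization idempotent on the 180 frame.

## Curvature candidates

Candidates are the strict local maxima of the curvature of the negated
pulse,

$$\kappa(x) = \frac{x''}{(1 + x'^2)^{3/2}},$$

restricted to zones where $p'' < 0$ (concave regions), endpoints excluded.
Derivatives are central finite differences on the unit-spaced index grid
(one-sided at the ends). Three numerical choices are interpretations, since
the reference states neither smoothing nor stencils:

* a width-5 moving average precedes differentiation (second differences
  amplify interpolation noise; 5 samples is far below the subpeak
  spacing). The average pads by linear extrapolation so a locally linear
  signal stays linear at the edges — partial windows would bend it and
  fabricate curvature there;
* the concavity gate uses the smoothed $p''$ with a small absolute
  tolerance ($p'' < -10^{-9}$): on segments flat to machine precision the
  sign of the second difference is round-off noise, not curvature;
* plateaus of the curvature contribute their left-most sample
  (deterministic tie-break).

## Pulse selection

Three trainable classifiers are provided (`selector_config()`), all ending
in a scalar logit passed through a sigmoid:

* **cnn** — three blocks of convolution → batch normalization → ReLU →
  max-pool (default channels 32/64/128, kernel 7, pool 2), then two dense
  layers (default first width 128) with ReLU between; dropout 0.2 at the
  end of the encoder and on the first dense layer;
* **lstm** — a single bidirectional LSTM cell over the 180 steps (hidden
  size 64), final states of both directions concatenated, then dense
  (128→64) and (64→1); dropout 0.2 after the cell and on the first dense
  layer;
* **lstm_fcn** — the convolutional encoder and an LSTM cell run in
  parallel on the same sequence, outputs concatenated into the two-dense
  head; dropout 0.2 on the first dense layer.

The reference figure giving exact layer widths is not available as
numbers; the defaults above are a deliberately small capacity consistent
with a ~10⁴-pulse training set, and all are configurable. Training
minimizes binary cross-entropy (numerically stable logit form) with Adam;
the defaults (`train_config()`) are 150 epochs, learning rate 0.001, batch
size 256, 10% validation split. The validation split is the last tenth of
a seeded shuffle; there is no early stopping (training always runs the
configured epochs). The ≈9:1 class imbalance is left unweighted by
default, matching the reference recipe's silence; `pos_weight` exposes
optional positive-class weighting. The operating threshold is chosen on
scores by `youden_threshold()`, maximizing TPR − FPR over the finite set
of midpoints between distinct scores (±∞ included), ties resolving to the
higher threshold (fewer positives kept). `roc_auc()` is the trapezoidal
area over the same sweep, equal to the Mann–Whitney statistic with ties
counting one half.

## Subpeak designation

For each labeled pulse the designation networks regress a 180-point target

$$y(t) = \tfrac12\left(e^{-(t-p_1)^2/2\sigma^2} + e^{-(t-p_2)^2/2\sigma^2}\right),$$

two unit-variance Gaussians centred on the labeled P1 and P2 (the printed
form of the target writes the signal amplitude inside the exponent, which
is dimensionally incoherent; the Gaussians-centred-on-the-positions
reading is implemented, with $\sigma = 1$ sample by default and a
`target_sigma` knob since unit-width targets are extremely sparse).
Training minimizes mean squared error under the same Adam recipe.

Two architectures (`designator_config()`):

* **lstm** — bidirectional cell with hidden size 180; the 360-dimensional
  concatenated state feeds dense layers (360, 360) and (360, 180), ReLU
  between, dropout 0.2 on the first dense layer (these dimensions are
  fixed by the architecture description);
* **unet** — a three-level 1-D encoder–decoder (default channels
  16/32/64, kernel 7), max-pool down, nearest-neighbour upsampling with
  skip concatenation between same-shape stages, convolution blocks of
  convolution → ReLU → dropout 0.2, and a final one-channel projection.

Designation reads the network output either **at the curvature
candidates** (the two highest-scoring candidates win; the output is read
exactly at the candidate index, with no neighborhood pooling — the
simplest faithful reading of scoring candidates by the output) or **at
its own local maxima** (`nn_output` mode). Score ties keep the earlier
index. P1 is the earlier of the two designated indices. Fewer than two
candidates or maxima makes the pulse non-calculable — a data condition,
not an error. A curvature-only baseline (`designate_curvature_baseline()`)
takes the two earliest candidates with no network. The ratio is computed
on the normalized pulse, i.e. amplitudes above the pulse minimum
(equivalently, raw amplitude above the diastolic minimum — the reference
never states the baseline; min-anchored normalization makes the two
readings identical).

## Postprocessing

The raw ratio series (missing where selection rejected a beat or
designation failed) is smoothed causally: for each beat with a full
trailing window of 100 pulses (≈1 minute), if at least 50 window values
are non-missing — counted **before** outlier exclusion — values outside
the 95% normal band $m \pm 1.96\,s$ (sample mean, $n-1$ standard
deviation) are excluded in a single pass and the mean of the remainder is
displayed; otherwise the output is missing. Single-pass, check-first is
the simplest reading of the procedure (iterated trimming is not
described). With fewer than two valid values no exclusion is attempted;
if all window values are equal the displayed value equals them for any
confidence level. The trailing window introduces the known display delay.

## The training engine

No deep-learning framework exists in this package's dependency stack, and
the networks are the heart of the method, so the engine is implemented
here: dense, 1-D convolution (im2col + BLAS), batch normalization,
max-pooling, nearest-neighbour upsampling, dropout (inverted, disabled at
inference), bidirectional LSTM, BCE/MSE losses, Adam, and global
gradient-norm clipping (default 5, stabilizing the recurrent nets early
in training). The LSTM recurrence — the only compute-heavy part — runs in
compiled single-precision kernels (Rcpp/RcppArmadillo), as is standard
practice for network training; everything else is double-precision R.
Every backward pass is verified against central finite differences in the
test suite. All randomness (initialization, shuffling, dropout) flows
from one integer seed through an isolated RNG scope, so training is
bit-reproducible.

## Problem sizes used by the tests and the acceptance script

The synthetic study conditions are: selector — 5000 training and 1000
held-out pulses with 10% non-calculable (the ≈9:1 imbalance of labeled
clinical sets), bidirectional-LSTM selector trained 12 epochs at batch 64;
designator — 3000 training and 500 held-out calculable pulses with target
ratios uniform in 0.6–1.4, LSTM designator trained 15 epochs at batch 64,
evaluated in curvature mode; onset recovery — four noiseless 60 s records
at 50–100 bpm. Epoch counts were fixed where training and validation losses
plateau consistently across seeds on these separable synthetic classes; batch 64 gives the
small datasets enough optimizer steps per epoch. These sizes are stated
here as the package's chosen benchmark conditions so that results are
reproducible; `train_config()` defaults remain the reference recipe (150
epochs, batch 256).

## Known limitations

* Performance numbers on synthetic data are upper bounds relative to
  clinical data: the generator's classes are more separable than real
  pulse quality grades.
* The curvature candidate set inherits the smoothing width; subpeaks
  closer than about three Gaussian widths are treated as unresolvable by
  construction.
* The LSTM kernels are single precision; gradients below ≈10⁻⁴ are at
  round-off level (immaterial for Adam-scale updates).
* Only 100 Hz-class sampling has been exercised; other rates work through
  the same code paths but are not part of the validated conditions.
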