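---
title: "Coupling-driven adaptive band selection for high-gamma ECoG decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling-driven adaptive band selection for high-gamma ECoG decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacband)
```

## The problem and the model

Electrocorticography carries task information far above the EEG range:
high-gamma activity (70–200 Hz) encodes movement and perception, but the
informative content typically occupies narrow, subject- and task-specific
sub-bands inside that wide range. A fixed 70–200 Hz filter dilutes those
sub-bands with broadband noise; a brute-force scan over candidate bands is
expensive and unstable at small trial counts.

`pacband` uses phase–amplitude coupling (PAC) as the physiological prior
for locating the informative sub-bands: the phase of a slow cortical
rhythm (delta 1–3, theta 4–8, alpha 8–12, beta 12–20 Hz) modulates the
amplitude envelope of faster, spatially local high-gamma activity. A
high-gamma sub-band whose envelope is locked to a slow rhythm during the
task is, by that token, participating in task-related cortical
coordination — so the coupling spectrum doubles as a band-relevance
spectrum, obtained *without using the class labels*.

### Event-related coupling

Averaged PAC indices assume stationarity over long stretches; event-locked
trials do not satisfy that. The event-related formulation instead fixes a
time point relative to the event and measures, **across trials**, the
circular–linear correlation between the instantaneous phase
$\phi_t$ of a slow band and the instantaneous amplitude $a_t$ of a
high-gamma bin:

$$
p_{cl} \;=\; \sqrt{\frac{r_{sx}^2 + r_{cx}^2 - 2\,r_{sx}\,r_{cx}\,r_{sc}}
                       {1 - r_{sc}^2}},
$$

with $r_{sx} = \mathrm{cor}(\sin\phi_t, a_t)$,
$r_{cx} = \mathrm{cor}(\cos\phi_t, a_t)$ and
$r_{sc} = \mathrm{cor}(\sin\phi_t, \cos\phi_t)$, all Pearson correlations
over trials. $p_{cl} \in [0, 1]$ is invariant under phase rotation and
under positive affine maps of the amplitude (`circular_linear_correlation()`;
both invariances are tested). Phases and amplitudes come from the Hilbert
analytic signal of zero-phase Butterworth bandpass output
(`hilbert_analytic()`, `bandpass()`).

Scanning the amplitude over a grid of high-gamma bins and stepping the
time point through the epoch yields a time × frequency coupling matrix per
channel and rhythm (`erpac_matrix()`).

### Band selection

`erpac_fbs()` runs the full selector per rhythm: coupling matrices are
averaged across channels, the time axis is compressed to a frequency
profile (maximum over time by default; the mean is available as
`selection$compression = "mean"` — the two conventions coexist in the
field and differ little on event-locked data, but the maximum preserves
transient task-locked coupling that averaging dilutes), the profile is
smoothed with a Savitzky–Golay filter (window 11 bins ≈ 22 Hz, polynomial
order 3: below the selection bandwidth so true peaks survive, above the
grid step so sampling jitter does not), and the strongest `n_peaks = 2`
strict local maxima become sub-bands $[p - \mathrm{BW},\ p + \mathrm{BW}]$
with $\mathrm{BW} = 10$ Hz. Ties in peak intensity break toward the lower
frequency; a profile with no interior maximum falls back to the full
analysis range (flagged `fallback_used`). Per rhythm, the selected
sub-bands are bandpassed and superimposed into one mixed signal
(`build_mixed_signals()`), optionally with the rhythm's own low-frequency
signal added (`include_low`, default `FALSE`: no consistent winner has
been established in either direction, and omitting it keeps the decoder
input purely high-frequency).

### The sideband-resolution constraint

Coupling at modulation frequency $f_1$ puts sidebands at
$f_{\mathrm{carrier}} \pm f_1$. An amplitude filter of full bandwidth
$\Delta f_2 < 2 f_1$ cannot pass both sidebands, so the envelope at the
true carrier looks *unmodulated*: a false negative exactly where the
coupling lives. This rule is why canonical gamma (30–50 Hz) is excluded
from the default rhythm list (it would need $\Delta f_2 \ge 100$ Hz), and
it also dictates the scan-grid bandwidth: with ±5 Hz bins, a 10 Hz (alpha)
modulator produces a coupling *null* at the carrier bin and twin peaks
±7 Hz away — we verified this directly on noiseless coupled signals. The
default grid (`amplitude_grid()`) therefore uses half-bandwidth 10 Hz
(bins of 20 Hz, centers every 2 Hz from 80 to 190), resolving modulators
up to the alpha band. Beta modulators (up to 20 Hz) formally violate the
rule even at this width; `check_bandwidth_constraint()` flags such
configurations but the beta rhythm is retained, matching field practice —
attenuated coupling is still detectable, and the advisory makes the
caveat explicit.

## The decoder

`build_pacnet()` constructs a compact convolutional classifier in the
EEGNet tradition, adapted to the filter bank: because the four mixed
signals are deliberately independent, the first temporal convolution is
**split into four parallel branches** (one per rhythm band, F1 = 8 kernels
each, kernel length = trial length / 4, i.e. half the sampling rate for
2-s epochs, batch-normalized) so features of different bands cannot
interfere before spatial mixing. The branch feature maps are concatenated
and passed through a depthwise spatial convolution over channels
(multiplier D = 2), ELU, average pooling (4), a separable temporal
convolution (F2 = 16, kernel 16), ELU, pooling (8), dropout (0.5) and a
dense softmax. `build_baseline()` is the identical trunk with a single
branch over the broadband 70–200 Hz signal — the ablation control.

The network is implemented directly in the package (forward and backward
passes over compiled 1-D convolution kernels, Adam at lr 1e-3, batch 16,
early stopping on validation loss with patience 30 over at most 300
epochs, best-validation weights restored). The backward pass is verified
against numerical differentiation in the test suite and the
training loop is exactly reproducible under a seed on CPU — no
framework-level nondeterminism exists. Training-set statistics drive the
batch normalization; running moments serve inference.

## Evaluation protocol

`evaluate_repeated_kfold()` runs repeated stratified k-fold
cross-validation: per repeat a fresh stratified partition; each fold is
the test set once, the next fold is the validation set, the remaining
k − 2 folds train the model. **Band selection runs inside each fold on the
training trials only** — the selection is data-driven, so running it
outside the loop would leak test information into the filter bank. The
harness is validated with forced-value factories (a majority-class dummy
must score exactly the majority fraction; a label oracle exactly 1) and a
leakage guard: permuting test-fold labels after training must drive
measured accuracy to chance while the same predictions still decode the
true labels. Decoders are compared with a paired one-sided t-test on the
matched per-fold accuracies (`paired_onesided_ttest()`, `compare_cv()`).

## The synthetic generator

`synthetic_spec()` / `generate_labeled_dataset()` emulate event-locked
ECoG trials with a controlled coupling ground truth:

$$
x(t) = A_m \sin(2\pi f_m t + \psi)
 + g\,A_c\,[1 + m \cos(2\pi f_m t + \psi + \varphi_0)]\,
   \sin(2\pi f_c t + \psi') + \varepsilon(t),
$$

with rhythm and carrier phases $\psi, \psi'$ drawn fresh per trial (so
coupling is invisible within any single trial and emerges only across
trials, which is precisely what the event-related statistic measures), a
pink (1/f, 80% of noise power) plus white noise floor, and defaults that
mirror the targeted recording regime: 1000 Hz sampling, 2-s trials, 8
channels of which 2 carry the carrier, $f_m = 10$ Hz, $f_c = 110$ Hz,
depth $m = 0.8$, noise calibrated analytically to 0 dB in-band (70–200 Hz)
SNR for a unit carrier. The default two-class design is "rest" (carrier
gain 0.25, no modulation) vs "active" (full carrier, depth 0.8), emulating
the severalfold task-locked high-gamma power increase of movement against
rest; a variance-collapse test verifies that class information vanishes
when the 100–120 Hz band is removed, so decoder results measure band
selection and not an artifact. What the generator does **not** model:
volume conduction and channel correlation, line noise and movement
artifacts, non-sinusoidal rhythm waveforms, drifting coupling phase, and
1/f slope changes between conditions. Passing tests therefore demonstrate
correctness of the machinery under the stated coupling model, not
performance on real recordings.

## Numerical choices

* **Filters.** Butterworth order 4 applied forward–backward (zero net
  phase, effective order 8). The design is computed in zero-pole-gain
  form and realised as cascaded second-order sections: the expanded
  transfer-function polynomial is catastrophically ill-conditioned for
  narrow low-frequency bands (an order-4 delta bandpass at 1000 Hz
  explodes past 1e16 in direct form).
* **Edge handling.** Signals are padded by min(1 s, length/4) per end
  before filtering and the Hilbert transform, then cropped. The default
  padding is a linear-predictive (Yule–Walker AR(24)) extension of each
  signal: it continues oscillations in phase across the boundary, where a
  plain mirror leaves a derivative kink whose ringing reaches percent
  level well inside a narrowband filter's output. Yule–Walker estimates
  are always stationary, so the extension cannot diverge. Because the
  fitted extension depends on the data, strict linearity of the filter is
  only guaranteed under `pad = "reflect"` (plain mirror), which all
  linearity tests use.
* **Hilbert transform.** Frequency-domain analytic-signal construction on
  the padded epoch; phase is `arg(z)` in (−π, π], zero at a cosine
  maximum.
* **Degenerate cells.** A time–frequency cell with zero amplitude or
  phase variance across trials is recorded as missing and excluded from
  time compression, never set to 0 (a spurious zero would masquerade as
  evidence of no coupling).
* **Smoothing near-zero tails.** Strict local maxima whose smoothed
  intensity is below 1e-6 of the profile maximum are discarded; they are
  floating-point wiggle, not peaks.
* **Overlapping sub-bands** within one rhythm are superimposed as-is
  (double-counting the overlap), matching the superposition definition;
  `merge_overlaps` unions them first when set.

## Problem sizes used by the tests and the acceptance script

Unit tests run at 250–500 Hz with 10–60 trials. The end-to-end checks use
the generator's native regime (1000 Hz, 2 s, 60 trials, 8 channels) for
band recovery (20 seeds per condition in the test suite, 10 in the
acceptance script) and a reduced two-class set (500 Hz, 1 s, 4 channels,
40 trials per class) with a narrower decoder (F1 = 4, F2 = 8, kernel 64,
25 epochs) for the ablation and leakage checks — sizes chosen so the full
pipeline, including in-fold selection, is exercised end to end many times
over. The ablation is directional (adaptive bands ≥ broadband baseline on
a task whose signal lives at 100–120 Hz); at these trial counts the gap's
magnitude is noisy even though its direction is stable.

## Known limitations

* Band selection aggregates coupling across channels by averaging; with
  few coupled channels among many, contrast shrinks linearly in the
  channel count. Per-channel selection is a natural extension not
  implemented here.
* Selection pools all trials handed to it. Pooling mixes condition-
  specific coupling; to select on one condition, subset the trial set
  first (`trials[labels == 1]`).
* The beta rhythm's sidebands are under-resolved at the default grid (see
  the constraint above); beta-driven selections are advisory-flagged.
* The EDF reader implements the common single-rate EDF/EDF+ layout
  (16-bit samples, one annotation channel); it does not resample
  mixed-rate files, by design.
* The decoder is CPU-sized; at the defaults it trains in seconds to
  minutes on desk-scale data, not tuned for large channel counts.
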