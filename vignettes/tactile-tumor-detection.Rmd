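---
title: "Tumor detection from temporal tactile-sensor output: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor detection from temporal tactile-sensor output: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palpassist)
```

## The problem

In laparoscopic surgery the surgeon cannot palpate tissue, so stiff
inclusions such as early-stage gastric tumors are easy to miss. One remedy
is computer-aided palpation: a slender tactile sensor is scanned over the
target and its output is analysed alongside whatever feedback the surgeon
receives. `palpassist` implements a detection assistant for that setting.
Its input is the time series of a single-element force-proxy sensor sampled
at 1 kHz and low-pass filtered at 10 Hz; its output is a per-trial decision
about whether a tumor was present, together with criterion-free measures of
detectability. The tumor of interest is toroidal (a 0-IIc superficial
ulcerative type), so a stroke crossing it produces two small peaks — one
per edge — on top of the contact baseline.

## Pipeline

### Sliding windows

The trace is cut into windows of width $T_w = 1.0$ s shifted by
$T_w - T_o = 0.1$ s. With `extraction_config()` both quantities must
resolve to whole samples. The shift gives a 10 Hz refresh rate; each
steady-state sample is covered by $T_w/(T_w - T_o) = 10$ windows, fewer
near the trial edges. No partial windows are created (the network input
dimension is fixed), so up to `shift - 1` trailing samples are covered only
by earlier windows. We use R's native 1-based indexing with closed
`[start, end]` sample intervals throughout; window starts are
$1, 1+s, 1+2s, \dots$.

### The segmentation network

A fully connected network with three hidden layers maps a window
$x \in \mathbb{R}^W$ to per-sample tumor probabilities:
$$h_i = \sigma(W_i h_{i-1} + b_i), \quad i = 1,\dots,4, \qquad
\sigma(z) = \max(z, 0),$$
with $h_0 = x$ and the output passed through an element-wise logistic
$y = 1/(1 + e^{-h_4})$. The reference geometry is $W = 1000$ with hidden
widths 2000 (a 1:2 input:hidden ratio that reduced geometries preserve).
Two deliberate numerical choices:

* **Output sign.** A sign-flipped logistic $1/(1+e^{+h_4})$ would make
  larger pre-activations yield *lower* probabilities, contradicting the
  probabilistic reading of the output; the standard logistic is the
  default and the flipped variant is available as
  `dnn_control(flip_output_sign = TRUE)` for comparison experiments.
* **Loss.** The default is the full binary cross-entropy
  $E = -\sum_k [t_k \ln y_k + (1-t_k)\ln(1-y_k)]$. The positive-term-only
  variant $E = -\sum_k t_k \ln y_k$ (mode `"positive_only"`) is degenerate
  — its optimum is $y \equiv 1$ regardless of the labels — and is kept
  only for comparison; the segmentation behaviour that makes trial scoring
  work requires the full form.

Training is authored in the package: He initialization (weights
$\mathcal{N}(0, 2/\mathrm{fan\_in})$, zero biases), mini-batch Adam
(defaults: learning rate $10^{-3}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$ — the canonical values, since nothing else is
specified for this setting), batch size 100, 200 epochs at reference
scale, windows reshuffled every epoch with the last short batch kept.
Probabilities are clipped to $[10^{-12}, 1-10^{-12}]$ inside the loss.
Because the sensor units are arbitrary, inputs are z-scored by default
using the training set's pooled mean and SD, stored in the fitted object
and replayed at prediction time (`dnn_control(normalize = FALSE)` turns
this off). Gradients are validated against central finite differences to
$10^{-5}$ relative error in the test suite.

### Trial scoring and the detection criterion

Window outputs are fused by overlap averaging: each sample's score is the
mean over all windows covering it (ten in steady state; at the trial edges
the mean runs over however many windows exist, rather than discarding the
boundary). Within each scanning segment the maximum score is taken, and
the mean of the per-segment maxima is the trial's representative score.
Scanning segments are recovered from the tangential contact force as
maximal runs above 10% of the trial's peak force, bridged across gaps
shorter than 0.1 s and kept if they last at least 0.3 s — the principle
(contact implies tangential force) is fixed but the constants are not
prescribed anywhere, so they are configurable and chosen to be robust on
the synthetic strokes. Samples outside every segment never contribute to
the trial score.

Detection compares the representative score against a criterion with a
strict inequality; equality counts as "no detection" (ties are otherwise
undefined by a larger/smaller rule, and the strict reading is the
conservative one). The criterion is calibrated from the accuracy curve
over the grid $c_j = 0.00, 0.01, \dots, 1.00$:
$$ACC_{th} = \max_j ACC_j - \frac{\max_j ACC_j - 0.5}{10}, \qquad
c_{th} = \frac{c_l + c_u}{2},$$
where $c_l$ and $c_u$ are the smallest and largest grid criteria whose
accuracy reaches $ACC_{th}$ (compared with $\ge$, so the maximizer always
qualifies). Two edge cases are worth noting. For a *below-chance* curve
($\max ACC < 0.5$) the formula puts $ACC_{th}$ above the maximum and no
criterion would qualify; the implementation lets the maximizer qualify and
warns, since such a curve signals a degenerate model. And for a
*multimodal* curve the global $c_l$/$c_u$ reading can place $c_{th}$ in a
dip between two qualifying regions; the guarantee
$ACC(c_{th}) \ge ACC_{th}$ therefore holds in the rule's intended unimodal
regime, and only the bracketing $c_l \le c_{th} \le c_u$ in general.

### Signal-detection evaluation

Hit and false-alarm rates over the same criterion grid trace an empirical
ROC curve. Anchor points $(0,0)$ and $(1,1)$ are appended when absent —
under the strict rule a score of exactly 0 is never detected, so $c = 0$
need not reach $(1,1)$ — and the pairs are sorted by $F$ (ties by $H$)
before integrating. The area $A_g$ uses the standard trapezoid
$\tfrac12 \sum_j (F_{j+1} - F_j)(H_{j+1} + H_j)$; a product-form variant
$\tfrac12 \sum_j \Delta F_j \, \Delta H_j$ exists behind
`roc_area(method = "increment_product")` but is not a proper area (it
yields 0 on the unit-square curve) and is never used by the pipeline. Note
the grid construction quantizes scores to 0.01 bins: the trapezoidal area
equals the rank-based (Mann–Whitney, ties $\tfrac12$) AUC exactly for
grid-aligned scores, and to within the bin resolution otherwise; likewise
invariance under strictly increasing score transforms is exact only for
transforms that respect the binning.

### Validation protocols

*Within-participant*: each participant's 40 trials are partitioned into
four class-balanced folds of ten. Stratification is forced by arithmetic:
the remaining 30 trials must support a 10-per-class training set and a
5-per-class calibration set, which requires 15 of each class outside every
fold. Per fold, the 30 remaining trials are split five times at random
into 20 training (dataset #2-1) and 10 calibration (dataset #2-2) trials;
each repetition trains a network and calibrates a criterion, the five
criteria are averaged, and the held-out fold is scored. *Across-
participant*: each participant in turn is fully held out; from every other
participant 13 trials per class go to training and the remaining 7 per
class to calibration (286 and 154 trials for a 12-participant cohort),
again five times.

Which model scores the test set is genuinely open — one could use any of
the five repetition models. We score with the *ensemble mean* of the five
models' score series, which treats the repetitions as symmetrically as the
averaged criterion does; `ensemble = "last"` reproduces single-model
behaviour. Information flows only forward: normalization statistics and
weights depend solely on dataset #2-1, the criterion solely on dataset
#2-2.

The human-comparison statistics (paired Wilcoxon signed-rank with a
Shapiro–Wilk normality check) are deliberately a thin hook,
`compare_with_human()`, around the standard `stats` routines: they only
make sense against per-participant human accuracies the user supplies.

## The synthetic phantom-scan generator

`scan_profile()`/`generate_trial()` emulate the recordings
phenomenologically, not biomechanically. Per stroke, the sensor trace
receives a half-sine contact bump (baseline amplitude ≈ 1 in arbitrary
units) and the tangential force a half-sine of the same extent; strokes
are separated by 0.2–0.5 s of zero force so that segment extraction is
actually exercised. A tumor crossing adds two Gaussian bumps of SD
`stroke_duration/10`, centred `tumor_peak_separation` apart around the
stroke midpoint, and labels the spanned interval 1; peak separation and
width scale with the realised stroke duration, so slow passes widen the
signature in time exactly as slow scanning does. Gaussian noise is added
before the zero-phase second-order Butterworth low-pass at 10 Hz (zero
phase keeps the labels aligned with the peaks; the label trace is not
filtered). Stroke durations and applied force jitter per stroke
(`speed_jitter`, `force_jitter`, default 10% each), and
`generate_cohort()` perturbs force scale, peak amplitude and stroke
duration log-normally between participants, emulating the inter-operator
variation in speed and force that motivates per-user calibration.

Defaults encode the recording conditions being emulated: 1 kHz sampling,
10 Hz cutoff, 3 strokes of 1.0 s per trial, noise SD 0.05, tumor-peak
amplitude 0.8, peak separation 0.3 s, and 40 trials per participant in a
randomized exact 20/20 present/absent split. No amplitude calibration or
SNR is reported for the real sensor, so amplitudes were chosen once to
make the two-peak signature visually comparable to the published example
traces, and are not revisited.

What the generator does *not* emulate: silicone/sponge mechanics and
sensor acoustics, drift or motion artefacts, label noise from imperfect
motion capture, strokes that miss the tumor, and participants' learning
over a session. Passing the end-to-end tests therefore shows that the
algorithmic chain recovers a detectable signature under controlled
conditions — not that the network would reach any particular accuracy on
real recordings.

## Problem sizes used by the tests

The shipped tests and acceptance checks run a reduced geometry chosen as
the package's desk scale: 40 Hz sampling (the lowest rate at which the
1.0 s / 0.9 s window geometry still yields whole-sample widths and shifts
with the steady-state coverage of ten), 2 strokes per trial, noise SD 0.02
against unit peak amplitude (a high-SNR regime), windows of 40 samples and
hidden layers of 80 (the preserved 1:2 ratio), 25 training epochs for
within-participant runs and 8 for the across-participant runs, whose
training sets are an order of magnitude larger. A 12-participant cohort
then exercises both protocols end to end in a few minutes of CPU time;
the no-signal control cohort (peak amplitude 0, 4 participants) checks
that accuracy and $A_g$ stay inside chance-level confidence bands —
binomial for accuracy, Hanley–McNeil null SD for the per-fold AUCs.

## Known limitations

* The full 1000/2000 reference architecture (~10M parameters) trains in
  plain R linear algebra; it is correct but slow — reduced geometries are
  recommended for experimentation.
* Inputs must already be sampled at the configured rate; there is no
  resampling, streaming extraction, or real-time engineering.
* The criterion rule's denominator 10 in the $ACC_{th}$ formula is an
  empirical constant of the method; no sensitivity analysis is attempted
  here.
* The figshare archive layout of the original recordings is not known to
  this package; `read_trials()` documents the expected tabular layout for
  anyone preparing real data, but no downloader or adapter is shipped.
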