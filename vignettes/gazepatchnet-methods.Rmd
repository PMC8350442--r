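---
title: "From raw gaze to expertise classes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw gaze to expertise classes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic data do and do not emulate, and the choices made where the
design was genuinely open.

## 1. Gaze geometry and fixation detection

Gaze is stored in normalized equirectangular coordinates: `u` in [0, 1)
maps to longitude λ = 360°·(u − 0.5) and `v` in [0, 1] to latitude
φ = 180°·(0.5 − v). Storing normalized coordinates decouples gaze files
from video resolution; conversion to pixels happens only at patch
extraction.

Angular velocity between two consecutive validly tracked samples is the
great-circle distance between the two gaze directions divided by their
time difference. The haversine form is used because consecutive gaze
samples at 250 Hz are typically fractions of a degree apart, where the
naive `acos` of a dot product loses several digits (the test suite's
independent oracle uses the `atan2` cross-product form instead, so the two
implementations share no code or formula).

The I-VT filter is implemented in its plainest reading: a sample is a
fixation sample iff its instantaneous speed is **strictly below 50°/s**;
maximal runs of fixation samples become fixations. Three edge conventions
had to be fixed:

* the comparison at exactly the threshold counts as a saccade (strict
  `<`), the common reading of a velocity *threshold*;
* the first sample of each contiguous valid segment carries no velocity
  and inherits the label of the transition into its successor; a singleton
  valid segment counts as a one-sample fixation (fixations with
  `n_samples ≥ 1` are legal);
* tracker dropouts (invalid samples) break velocity pairs and therefore
  split fixations — interpolating across dropouts would be an unvalidated
  invention. Invalid samples are retained in the stream, flagged, so the
  tracking ratio stays computable; they are excluded from all velocity
  and fixation computation.

No minimum fixation duration, no merging across short saccades and no
velocity smoothing are applied: the protocol names only a velocity
threshold, and anything more would be invention.

A trial enters the pipeline only when its tracking ratio is **strictly
greater than 0.75**.

Fixation centers are arithmetic means of the member samples, except the
horizontal coordinate, which is averaged circularly (unit-vector mean of
longitudes): a fixation straddling the u = 0/1 seam must center at the
seam, not at 0.5.

## 2. Patch extraction

The stimulus frame at a fixation's *temporal center* (`floor(ts·fps/1e6)`,
clamped to the last frame) is cut to a 224 × 224 × 3 patch centered at
pixel `(round(u·W) mod W, min(round(v·H), H−1))`, with pixel `(i, j)`
spanning `[i, i+1) × [j, j+1)`. Horizontal indices wrap modulo the frame
width — the equirectangular frame is a full horizontal turn, so the seam
is a spherical continuation — while vertical indices clamp with edge
replication at the poles. Zero-padding would inject artificial high-contrast
edges that a CNN would latch onto; replication and wrapping keep border
patches statistically similar to interior ones. Whether the original
protocol reprojected border patches is unstated; raw equirectangular crops
are used, and the choice of the temporal-center frame (rather than the
onset frame) follows the centered fixation representation.

No R bindings to video codecs exist in this package's dependency set, so
stimuli are either procedural scenes rendered on demand (any pixel window
of any frame can be evaluated directly, so patch extraction never decodes
a full frame) or directories of numbered PNG frames, which serve as the
on-disk interchange format.

## 3. Augmentation

Each sequence gains exactly one augmented copy, doubling the dataset while
preserving labels, ordering and identity. Per patch, in order: Gaussian
blur with σ drawn uniformly from [0.5, 2] px; salt-and-pepper noise on 2%
of pixel locations (black/white with equal probability); then **one**
geometric action drawn uniformly from {rotate, shear, rotate+shear,
flip-x, flip-y, translate-x, translate-y}, with rotation in ±180° and
shear in ±15°. Blur σ and noise density are not stated by the protocol and
are package defaults, exposed in `augment_spec()`. The stated translation
range of ±80 is interpreted in **pixels**: degrees are not meaningful for
in-plane patch translation, and ±80 px is about a third of the patch
width. Whether each patch received an independent geometric draw or one
draw per sequence is ambiguous; independent-per-patch is the default,
per-sequence is available (`geometric_per_sequence = TRUE`). Geometric
warps use inverse-mapped bilinear sampling with clamped coordinates, i.e.
edge replication rather than constant fill, for the same reason as patch
borders. Augmentation runs offline, before any training.

## 4. Feature extraction

A backbone maps one 224 × 224 × 3 patch to a 1,024-vector and owns its own
preprocessing contract (backbones disagree about normalization, so the
patch store stays normalization-free). Two backbones are registered:

* **googlenet-pool5** — the GoogLeNet architecture (stem, nine inception
  modules, global 7 × 7 average pool) truncated before all classification
  layers; its final pool emits exactly 1,024 channels. Weights are
  He-initialized under a fixed seed; the architecture, not a particular
  ImageNet fit, is what the package's shape guarantees rest on, and
  pretrained weights can be loaded into the same structure where
  available. Inputs in [0, 1] are rescaled to [−1, 1].
* **toy** — foveated pooled statistics: per-channel cell means and SDs
  over concentric grids (7 × 7 on the full patch, 5 × 5 on the central
  half, 3 × 3 on the central quarter, one central cell; 336 numbers),
  projected to 1,024 dimensions by a fixed seeded **sparse sign
  projection** (each output dimension is a signed copy of one statistic;
  every statistic appears at least once). Two design points matter: the
  fixated object sits at the patch center by construction, so
  center-weighted pooling preserves its signature instead of diluting it
  across the wide equirectangular crop; and the sparse projection keeps
  the statistics axis-aligned — a dense random projection mixes the few
  informative statistics into every dimension, which small-sample
  downstream models demonstrably cannot un-mix. Deterministic,
  dependency-free, and two orders of magnitude faster than the CNN; the
  default for tests and desk-scale experiments.

## 5. The sequence classifier

The classifier is a bidirectional LSTM over the per-fixation feature
sequence: sequence input (1,024) → BiLSTM with 500 units per direction →
concatenation of the two directions' final steps (1,000) → fully connected
(100, linear) → dropout 0.5 (training only) → fully connected (3) →
softmax, cross-entropy loss. Per direction the LSTM holds a 2,000 × 1,024
input block, 2,000 × 500 recurrent block and 2,000 biases; stacked across
directions these are the 4,000 × 1,024, 4,000 × 500 and 4,000 × 1 blocks
reported by `summary()`. (The architecture's prose description elsewhere
gives "50" and "13" hidden units, which contradict these printed weight
shapes and the 1,000/100 activation counts; the shapes win.)

Training follows the published options: minibatch 42, constant learning
rate 4.4e-4, L2 8.2e-4, validation every 52 iterations, patience 6,
maximum 100 epochs, no reshuffling between epochs. Open points resolved
here:

* **Optimizer** — unspecified; Adam with the stated constant rate is the
  default (compatible with "no learning-rate schedule"); plain SGD is
  selectable.
* **L2** applies to weight matrices only, not biases (common convention).
* **"Validation frequency 52"** is implemented literally as
  every-52-iterations; for the original dataset size that coincides with
  once per epoch.
* **Early stopping** halts when the validation loss is ≥ the running best
  at six consecutive checks. Which weights the fit returns is selectable
  (`checkpoint`): `"best"` restores the best-validation-loss checkpoint
  (the package default), `"final"` returns the last iterate, which is
  what MATLAB-style trainers return unless configured otherwise. The
  distinction matters at small validation sizes, where cross-entropy can
  rise through overconfidence while accuracy still improves, making the
  "best" checkpoint an early, undertrained iterate; the desk-scale
  configuration therefore uses `"final"`.
* **"Shuffle no"** is read literally: minibatch order is never permuted
  (a reading where only validation membership is fixed is selectable via
  `shuffle = TRUE`).
* **Padding** — the longest ~2% of sequences are removed (only sequences
  strictly longer than the longest retained one, so an equal-length set
  loses nothing), the rest are sorted ascending by length and padded with
  zero vectors; the "final step" the BiLSTM emits is the last *true* step
  of each sequence, never a padded one, which makes predictions invariant
  to padding length. The 2% removal happens once, before any
  train/validation/test splitting.
* Gradients are exact BPTT (verified against finite differences in
  development), and fits are bit-for-bit reproducible given a seed and
  single-threaded BLAS.

## 6. Evaluation protocol

One run per participant: all of that participant's sequences are held out;
the remaining participants' originals are split 70:30 into training and
validation; the augmented copies of the training originals join the
training side only; training classes are balanced by random undersampling
to the minority count. The held-out participant's *original* sequences are
predicted by the fitted model. Reported are the pooled 3 × 3 confusion
matrix (rows = true), per-class recall, one-vs-rest ROC/AUC over pooled
scores (threshold sweep with tie grouping, trapezoidal integration — which
equals the Mann–Whitney pair-counting statistic), the unweighted mean of
per-run accuracies, and the pooled accuracy. The last two are different
statistics and are both reported, uncorrected: a run-mean over unequal
held-out sizes does not equal trace/total of pooled counts. The split is
stratified by class by default (at desk scale an unstratified 30% draw can
produce single-class validation sets); a flag disables it. Per-run seeds
derive deterministically from (global seed, participant ID).

## 7. The synthetic cohort

The generator emulates the targeted study design: 250 Hz gaze over
equirectangular stimuli of a build-up scene — one small bright "ball"
disc, five teammate-colored and five opponent-colored discs moving slowly
(≤ ~6°/s) over a textured background — with three expertise classes.
The class signal lives in *both* pathways on purpose, and the default
profiles are deliberately **widely separated** — that separation is the
stated condition under which the desk-scale protocol must recover the
classes: dwell durations (novice 180 ± 40 ms < advanced 320 ± 70 ms <
expert 500 ± 110 ms) for the temporal pathway, and per-disc preferences
(novice uniform over all objects; advanced 2:3:1 for ball:teammate:
opponent; expert 8:4:0.25, i.e. opponents are fixated rarely) for the
spatial/appearance pathway.
Gaze noise is a per-fixation angular offset (calibration error; novice
1.2° > expert 0.5°) plus 0.02° per-sample jitter. White per-sample noise of
realistic magnitude would masquerade as saccadic velocity at 250 Hz, which
real tracker noise does not, so it is deliberately absent. About 3% of
samples are flagged invalid in short bursts. Saccades are short (~16 ms)
great-circle transitions, always to a *different* disc, so the planned
fixation count is recoverable exactly by the I-VT filter on noise-free
streams — the closed loop the oracle tests exploit.

Defaults are desk-scale: 4 participants per class × 8 trials over 4 shared
videos of 8 s at 960 × 480 (the same normalized gaze coordinates as the
3,840 × 1,920 reference; a 224 px patch then covers a larger visual angle,
which is acceptable for testing and flagged here as a deliberate
reduction). What passing desk-scale tests shows is that the pipeline's
plumbing, protocol hygiene and learning dynamics are sound; it does not
show that real athletes' expertise is recoverable at any particular
accuracy — the synthetic classes are far more stereotyped than human gaze,
there is no head movement, no scene semantics, and the toy backbone sees
color statistics rather than learned object features.

## 8. Desk-scale configuration and problem sizes

The full-fidelity model (500 units/direction over 1,024-d features,
~6.2 M parameters) is what `gazenet_config()` builds by default and what
the architecture audit checks. For cohort-level experiments and tests the
package uses a reduced configuration: hidden 16/direction, fc 25, dropout
0.5, minibatch 16, Adam at 1e-3, L2 1e-2, validation every 20 iterations
with patience 10, at most 400 epochs, with epoch shuffling (the
batch-order reading of the shuffle option; with ~5 minibatches the
literal fixed order yields class-skewed batches). It is sized for ~100-sequence training sets of toy
features, where the full model is massively over-parameterized and slow
without methodological gain; two diagnostics that shaped it are worth
recording. First, at these sample sizes the network's validation loss can
rise through miscalibration while its validation *accuracy* is still
improving, so the loss-based patience rule ends training early and the
best-loss checkpoint is an early iterate — denser validation checks and a
moderate learning rate mitigate this. Second, balanced undersampling plus
fixed, length-sorted batch order concentrates classes within batches,
which epoch shuffling repairs. The leave-one-participant-out acceptance experiments
run 12 participants (96 trials, ~20–40 fixations each) with the toy
backbone; with the default class profiles the mean LOPO accuracy must
exceed 80%, and with all three class profiles set identical it must stay
inside the 95% binomial band around 1/3 — the leakage control that guards
the protocol (a split that leaked augmented copies or participant identity
would push it above chance).

## 9. Known limitations

* No pretrained CNN weights ship with the package; the
  GoogLeNet-architecture backbone guarantees shapes and determinism, not
  ImageNet feature quality.
* The vendor's original event filter may have applied denoising or
  minimum-duration rules beyond the 50°/s threshold; these are
  unknowable from the protocol and not reproduced.
* Native gaze coordinates of the original recordings (angular vs.
  normalized) are unstated; the normalized convention is a repository
  decision.
* Video IO is PNG-frame-directory or procedural only; feeding real MP4
  stimuli requires decoding frames to PNG externally.
* GRU/plain-LSTM ablations and hyperparameter search are out of scope;
  hyperparameters are fixed to the published values.
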