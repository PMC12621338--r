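---
title: "kneeadl: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kneeadl: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kneeadl)
```

This vignette is the package's own account of its science: what each stage
assumes, which tunable parameters matter and why their defaults are what
they are, what the synthetic data generator does and does not emulate, and
where the design was genuinely open.

## 1. Problem setting

Two IMUs (3-axis accelerometer in m/s², 3-axis gyroscope in deg/s) are
embedded in the femoral and tibial components of a knee prosthesis and
stream at 50 Hz. The task is to classify 3-second windows of the combined
12-channel signal into eight activities of daily living. Two properties of
the acquisition drive the pipeline design: the devices *start
asynchronously* (they are powered independently and connect over radio),
and *samples are occasionally missed*.

## 2. Synchronisation model

Both streams are mapped onto a shared grid of 100 ms bins anchored at the
recording epoch (`t = 0`), not at either device's first sample — a shared
origin is what makes the two devices comparable at all. Bin `k` covers
`[100k, 100(k+1))` ms and retains the most recent sample *strictly before*
the upper boundary; a sample exactly on the boundary belongs to the next
bin, the natural reading under half-open intervals.

Empty bins are not mentioned in the original description, which only says
each bin keeps the most recent sample. Carrying the previous retained
sample forward is the natural extension of that rule, but unbounded
carry-forward would fabricate data across long outages, so a run of more
than `max_gap = 3` empty bins (300 ms) on either device splits the series
into separate segments. Three bins bridges isolated missed samples and
short radio hiccups at 1% dropout while refusing to invent more than
300 ms of signal.

Windows are 30 consecutive frames (3 s). The default stride is 30
(non-overlapping): overlap was never specified, and non-overlapping
windows cannot leak shared frames between training and test. A smaller
stride remains available for training-set augmentation.

## 3. Filtering

Filtering operates on the binned 10 Hz series (the stage is described
after synchronisation in the source pipeline), so the effective Nyquist is
5 Hz. Neither cutoffs nor orders were published; the defaults are set from
the signal content:

* **Accelerometer low-pass, order 4 at 2 Hz.** The fastest simulated
  cycle rate is 1.4 Hz (jogging); locomotor content lies at or below
  ~2 Hz while footstrike transients and vibration sit above. DC must
  be preserved because gravity orientation is the main information in
  the accelerometer channels.
* **Gyroscope high-pass, order 2 at 0.25 Hz.** Gyroscope bias and its
  random walk occupy the lowest decades; 0.25 Hz sits comfortably below
  the slowest activity rate that must pass (0.56 Hz stairs; the 0.13-0.16
  Hz transitions are attenuated but remain strongly classifiable from
  their large amplitude and the accelerometer path).

Both are Butterworth filters designed by bilinear transform (identical
coefficients to scipy/matlab `butter`, verified in the tests) and applied
forward-backward (zero phase), so the magnitude response is squared and
no phase lag distorts the window timing. Note one subtlety, frozen into
`butter_gain()`: near Nyquist, the digital filter's response follows the
*pre-warped* closed form `1/sqrt(1 + (tan(pi f / fs)/tan(pi fc / fs))^2n)`,
which attenuates much harder than the analog textbook formula — at 4 Hz
the order-4/2 Hz low-pass passes 0.3%, not 6%.

Edges are handled by odd-reflection padding of up to one window length
(30 samples), which preserves endpoint values and slopes; filtering runs
per contiguous aligned segment *before* windows are cut (fewer edge
transients than per-window filtering; a per-window entry point exists).
A series must be at least three times the filter order long.

## 4. Spectrogram tensor

The published constraint is the shape: 8 × 8 × 12. From 30 samples, the
minimal standard short-time Fourier settings realising it are segment
length 8, hop 3 (`floor((30-8)/3)+1 = 8` frames) and transform length 14
(`14/2+1 = 8` one-sided bins), with a periodic Hann taper. Power is scaled
`log(1 + power)`: bounded at zero power, no dB floor constant. These
parameters ride along in the tensor's `params` attribute.

One consequence of zero-padding an 8-sample segment to 14 points is
spectral leakage: a constant signal concentrates its energy in the DC row
but does not vanish exactly in the neighbouring rows. The tests assert
DC-row dominance and negligible upper-half power rather than exact zeros.

Both branches see the *same filtered input* (the architecture-defining
description), with a configuration switch to compute spectrograms from raw
windows instead.

## 5. Classifier

The architecture follows the printed layer sizes exactly: LSTM 384 then
256 units with 20%/45% dropout on their outputs (rates paired with layers
in printed order); convolution 128 filters 3 × 3 ("same" padding), max
pooling, 40% dropout, a 256-unit dense layer *before flattening*;
concatenation; 256-unit ReLU fusion; 8-way softmax.

Two points were genuinely open:

* **"Dense before flattening."** Read literally, the dense layer acts
  before the flatten — implemented as a position-wise (1 × 1) projection
  of the 128 pooled filters to 256 units at each of the 4 × 4 spatial
  positions, then flattened (4096 features). This is an unusual ordering
  and may be a description slip; `cnn_dense_after_flatten = TRUE`
  provides the conventional flatten-then-dense variant. Neither is
  asserted to be the original authors' intent; the literal reading is the
  default. Parameter counts for both are pinned in the tests (default:
  2,429,576).
* **Pooling size** is unstated; 2 × 2 is the only standard choice for an
  8 × 8 map ahead of a dense stage.

Training hyper-parameters (epoch count, batch size, learning rate) were
not reported. Defaults: Adam at 1e-3, batch 32, early stopping on
validation loss (the benchmark schedule caps at 50 epochs, patience 10),
best-validation-epoch weights retained. Initialisation is Glorot uniform
with forget-gate biases of 1. The engine is written in R directly on BLAS
matrix products (time-stacked LSTM so the input projection and all weight
gradients are single large GEMMs); gradients of every layer are verified
against central finite differences in the test suite.

Both the time-domain windows and the spectrogram tensors are standardised
per channel using statistics computed from the *training split only*,
stored with the model, and reapplied at inference. Window standardisation
is not part of the published description but is practically required:
gyroscope channels reach hundreds of deg/s and would saturate the LSTM
nonlinearities.

## 6. The synthetic data generator

The original cadaveric dataset is unavailable, so the generator is a
first-class module that stands in for it. Its defaults are the stated
acquisition conditions: 50 Hz, 100 repetitions per class, asynchronous
start (uniform 0–200 ms), 1% dropout.

Knee flexion per class is a raised cosine between the published range
bounds at the published rate; walking/jogging/stairs are continuous
multi-cycle recordings, the sit/stand/knee-bend transitions single
half-cycle ramps from the neutral posture (with a 0.6 s lead-in and a
hold, so every repetition spans at least one analysis window), and
standing still is a low-amplitude quasi-static oscillation. Rigid-body
kinematics distribute flexion over the segments: the femoral orientation
is `femoral_share * theta` plus a thigh-inclination profile, the tibial
orientation follows from the flexion identity `tibial - femoral = -theta`
exactly. The per-class femoral shares are the package's own choice,
set once from gross biomechanics and never revisited: stair ascent is
thigh-dominant (0.45) and descent shank-dominant (0.25) — lifting the
body versus controlled lowering; walking/jogging 0.35; knee bending keeps
the thigh near vertical (0.10); sit/stand transitions (0.30) additionally
ramp the thigh 0→90° synchronously with the flexion ramp, driven by the
normalised flexion progress so the coupling is exact on any time grid.

Each device then observes: gravity rotated by its segment orientation
(knee flexion axis = sensor x, gravity along sensor −z at full extension —
the real mounting orientations inside the prosthesis chambers were never
published, so a fixed convention is required and documented), lever-arm
tangential and centripetal terms (5/4 cm arms — the sensors sit inside
the implant, centimetres from the joint line), white noise (0.5 m/s²
accelerometer, 1 deg/s gyroscope — consumer-IMU magnitudes), a gyroscope
bias random walk (0.05 deg/s/√s), and, for jogging, exponentially
decaying footstrike spikes (3 m/s², 50 ms time constant) standing in for
the vibration content of a hydraulic rig.

**What a green benchmark does and does not establish.** The synthetic
classes differ in amplitude, frequency, transient shape and thigh
kinematics by construction; they carry none of the soft-tissue artifacts,
inter-repetition variability, tracking error or load-dependent deformation
of a cadaveric experiment. The synthetic benchmark therefore checks that
the *pipeline* — synchronisation, filtering, features, model, evaluation —
can realise the published performance level on data at least as separable
as the original, not that the published numbers are reproduced. Perfect
scores on it are expected of a correct implementation, and the acceptance
thresholds (accuracy ≥ 95.68%, macro F1 ≥ 0.96, F1 = 100% on the four
static/transitional classes) are met with margin rather than tuned to.

A further stated-world consequence: at 100 repetitions per class, slow
activities produce more windows than fast ones (a standing-still
repetition lasts 10 s, a jogging cycle 0.7 s), so the window counts are
imbalanced in the simulator's favour of standing still — mirroring the
moderate class imbalance of the original test table, and handled by the
stratified, recording-grouped split.

## 7. Split and evaluation

Fractions 0.70/0.11/0.19 with largest-remainder rounding (remainders to
train, so tiny classes never lose windows). The default benchmark split is
*grouped by recording*: all windows cut from one recording land in one
split, because adjacent windows of the same repetition are strongly
correlated and splitting them across train and test would leak. Whether
the original evaluation respected repetition boundaries is unknown; the
leakage-safe choice is the defensible default, and it is the harder one to
score well under. Metrics are reported at full precision in JSON and
rounded to two decimals in the CSV table, which mirrors the published
results-table layout.

## 8. Numerical and degenerate-input choices

* Integer-millisecond timestamps: the 100 ms binning arithmetic is exact,
  with no float-boundary ambiguity.
* Stream CSVs print six fixed decimals, so equal streams are equal bytes
  (golden-file tests rely on this).
* Classification ties break to the lowest class index, deterministically.
* Standardisation floors SD at 1e-8; a constant channel maps to zero.
* Filters refuse series shorter than 3 × order instead of padding
  heuristically.
* All randomness flows from one master seed through fixed
  multiplicative-congruential substreams (always < 2³¹), so every stage is
  reproducible and changing the master seed changes all of them.

## 9. Known limitations

* The simulator is sagittal-plane only: off-axis gyroscope channels carry
  noise, not cross-talk; real implant kinematics include small
  varus/valgus and rotation components.
* Waveforms are strictly periodic within a recording; there is no
  cycle-to-cycle variability beyond sensor noise, which overstates
  separability relative to human movement.
* The LSTM runs at the binned 10 Hz rate over 30 frames; very short
  transients between bins are invisible to both branches by design.
* Training the full-size model in R takes ~10 minutes on one CPU for the
  default benchmark; the engine is adequate for desk-scale experiments,
  not for GPU-scale work.
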