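---
title: "Methods: 3-second raw-ECG stress classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3-second raw-ECG stress classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Acute stress modulates the autonomic nervous system, and the
electrocardiogram carries that signature: heart rate rises and
beat-to-beat variability falls as sympathetic drive increases. `ecgstress`
classifies *raw*, ultra-short (3 s) single-lead ECG windows into two
(no-stress / stress) or three (low / moderate / high) stress levels with
small 1D convolutional networks, so that predictions can be produced in
real time on low-power hardware. No filtering and no handcrafted
heart-rate-variability features are computed: the windows enter the
network as sampled voltages.

Two public study designs motivate the two ingestion pipelines:

* **Driving protocol** (496 Hz ECG): each subject completes seven
  consecutive events — an initial rest, alternating city and highway
  driving, and a final rest.  A low-rate (15.5 Hz) marker channel carries
  a pulse at each of the 8 event boundaries.  Task difficulty fixes the
  labels: rest is low stress, highway moderate, city high.
* **Fear-exposure sessions** (100 Hz ECG): subjects watch a sequence of
  spider clips; a `triggers.txt` file gives each clip's start and end
  time.  No task-based labels exist, so clips are annotated from the
  subject's *own* heart-rate distribution (details below).

## Pipeline

1. **Ingestion** (`read_record`, `resample`).  WFDB-style `.hea`/`.dat`
   pairs are read at native frequencies; channels are moved between the
   two analysis frequencies (100 and 496 Hz) by Fourier resampling:
   the spectrum is truncated or zero-padded so the output has exactly
   `round(n * fs_out / fs_in)` samples.  This preserves a constant signal
   exactly and keeps band-limited content intact, which matters because
   the marker pulses must keep their ordinal peak positions after the
   15.5 → 496 Hz upsampling.  Any invalid (NaN) sample in a requested
   channel rejects the record rather than imputing: corrupted drives are
   excluded, not repaired.
2. **Drive segmentation** (`detect_marker_peaks`, `validate_drive`,
   `segment_drive`).  Marker peaks are local maxima above half of the
   signal range, at least 60 s apart — events last minutes, so genuine
   boundary peaks are far apart, and the polarity is flipped first if the
   extreme deviations point downward.  A drive is usable only with
   exactly 8 distinguishable peaks and an intact ECG; a configured
   per-subject discard list (manual inspection, not inference) turns a
   drive with known-bad leading events into a partial one.  Segments are
   half-open intervals `[peak_i, peak_{i+1})`, so boundary samples are
   never double-counted.
3. **Clip annotation** (`estimate_hr`, `annotate_clips_subject_based`).
   R peaks are detected on the moving-average-detrended trace (0.6 s
   window): candidates are local maxima above half of a rolling maximum
   evaluated on ~2 s chunks, thinned by a 0.25 s refractory rule where
   larger peaks win.  The rolling *maximum* — rather than a high
   percentile — is used deliberately: every 2 s chunk contains at least
   one R peak above 30 bpm, so the threshold tracks the R amplitude and
   stays safely above the T wave, whose amplitude is roughly a quarter of
   the R wave; a percentile threshold drifts into T-wave territory at low
   heart rates and double-counts beats.  Each clip's mean heart rate is
   z-scored within the subject, clips are sorted (stable on ties), and
   the lowest/middle/top thirds become LOW/MODERATE/HIGH
   (`ceiling(n/3)` clips for LOW and MODERATE, remainder HIGH).  Because
   z-scoring removes scale and offset, the labels are invariant under any
   affine transform of a subject's heart rates.  This annotation *assumes*
   a monotone heart-rate–stress relation within subject; on real
   fear-exposure data that assumption is fragile, so conclusions from
   this pipeline should be drawn with care.
4. **Baseline normalization** (`baseline_normalize`).  The mean of each
   subject's low-stress (baseline) recording is subtracted from *all* of
   that subject's segments, removing individual offset bias (electrode
   placement, posture, physiology).  Normalization runs on full segments
   before truncation or windowing, and is idempotent.
5. **Windowing** (`truncate_central`, `fragment`, `sliding_windows`).
   Event segments are truncated to their central 5 minutes (equal margins
   dropped; an odd remainder loses its extra sample at the end), which
   equalizes each subject's contribution and discards boundary noise;
   the shortest protocol event (5.12 min) still fits.  Segments are then
   cut into non-overlapping 3 s windows (`floor(L/w)` of them, anchored
   at the segment start).  Training sets may instead use overlapping
   crops at a fixed stride — 80 samples at 100 Hz, 150 at 496 Hz —
   giving `floor((L - w)/s) + 1` windows per segment.
6. **Splitting** (`make_split`, `make_folds`).  The unit of splitting is
   the *event segment*, never the window: sliding-window crops of one
   segment are near-duplicates, and a window-level split would leak them
   across partitions.  Segments are shuffled under a seed and assigned
   60/20/20; the train+validation pool is cross-validated with 4
   round-robin folds.  Folds are subject-agnostic by design: a fold can
   hold segments of several subjects and a subject can appear in several
   folds, matching the hypothesis that cross-subject ECG patterns exist.
   Validation and test partitions always use non-overlapping fragments.

## The two architectures

**Single-stage CNN** (`build_single_cnn`).  One valid 1D convolution
(32 filters), max-pooling with stride equal to the pooling length,
leaky-ReLU, then a 128-unit dense layer, dropout (0.5) and a softmax
head.  The kernel and pooling lengths are tied to the ECG period:

| `fs` (Hz) | window | kernel (0.6 s) | pooling (0.8 s) |
|----------:|-------:|---------------:|----------------:|
| 100       | 300    | 60             | 80              |
| 496       | 1488   | 300            | 400             |

The kernel spans one PQRST complex without reaching into the next beat;
the pooling spans at least one average heart period, so the maximum
response is extracted wherever the R peak falls within the pooling
window.  For a strictly periodic input whose period does not exceed the
pooling span, the post-pooling feature map is invariant to sub-period
phase shifts of the input — the property that makes a single
convolutional stage sufficient.  At 496 Hz with a 3-class head this
network has 18,339 trainable parameters.

**VGG-inspired CNN** (`build_vgg_cnn`).  Five stages of (same-padded
convolution of kernel 3, batch normalization, leaky-ReLU, max-pooling of
size 2, dropout), with channels 64–128–256–512–512, then global average
pooling and a dense softmax head: 1,308,675 parameters at the 3-class
head.  Inputs must survive five halvings (≥ 32 samples).

Layer widths the source descriptions leave open were fixed once: 32
filters and 128 hidden units for the single-stage net (the printed model
sizes, 28,866 and 1,554,819, are treated as upper bounds — no integer
configuration of the described topology reproduces them exactly), kernel
3 and pooling 2 per VGG stage (the usual VGG convention), leaky-ReLU
slope 0.01, dropout 0.5, batch-norm momentum 0.1 and epsilon 1e-5.  A
leaky-ReLU is placed after the hidden dense layer of the single-stage
net — the layer listing it derives from names no activation there, but
two stacked linear layers would collapse to one; the parameter count is
unaffected.  Convolution order is conv → pool → activation; with a
monotone activation, pooling and activation commute, so this choice
changes neither parameters nor outputs.

Training uses Adam (learning rate 1e-3), batches of 64, at most 50
epochs with early stopping on validation accuracy (patience 10), and
cross-entropy loss.  No class reweighting is applied even though the
corpus is slightly unbalanced, matching plain accuracy reporting.  All
randomness — shuffling, dropout, initialization — derives from explicit
seeds, so training histories are exactly reproducible.  The layers,
backward passes and optimizer are implemented in the package itself on
top of BLAS matrix products (convolution via im2col), keeping the whole
pipeline dependency-light and deterministic.

## The synthetic generator

`generate_ecg` renders each beat as five Gaussian bumps (P, Q, R, S, T)
at fixed phase fractions of the local RR interval, R dominant, with
additive Gaussian noise and a per-subject constant offset.  Stress
classes separate the way the real annotation logic assumes they do:
through mean heart rate (defaults LOW 60, MODERATE 80, HIGH 110 bpm)
and, secondarily, through RR variability, which is *higher* at rest
(fractions 0.10 / 0.06 / 0.04) because stress withdraws vagal tone.
Per-beat heart-rate jitter has a 2 bpm standard deviation, the R
amplitude is 1 mV and the noise standard deviation 0.03 mV — values a
clean lead-II chest recording would produce.  `generate_drive` emits the
full seven-event protocol (event durations drawn from 5.5–7 min so the
5-minute truncation always fits, with the 5.12-min study minimum
respected) plus a 15.5 Hz marker with 0.8 s square pulses at the 8
boundaries; `generate_spider_subject` emits 60 s clips whose heart rates
cycle through the class means, with the matching trigger file.

What the generator does *not* emulate: pathological morphologies, motion
artifacts, electrode pop, baseline wander, respiratory modulation, or
the overlap of class heart-rate distributions seen in real subjects.
Passing the recovery experiments therefore shows that the pipeline and
the networks work end to end and can extract rate-coded class structure
from raw windows — not that the printed real-data accuracies transfer.
Reproducing those requires the original recordings through the same
ingestion path.

## Numerical choices and degenerate inputs

* Fourier resampling handles the shared Nyquist bin explicitly (split on
  upsampling, folded on downsampling) and rejects signals shorter than
  2 samples.
* Peak, split and fold routines are deterministic under ties: `order` is
  stable, argmax ties resolve to the lowest class index.
* Flat markers (`NoPeaks`), flat ECG spans (`NoBeats`), missing baseline
  segments, identical clip heart rates (`ZeroVariance`), empty datasets
  and mismatched class spaces or window lengths raise classed conditions
  rather than producing silent nonsense.
* Windows are exactly `round(3 * fs)` samples; a segment shorter than
  one window is an error, not an empty result.

## Problem sizes used by the test suite

The shipped tests run entirely on synthetic data: the corpus-arithmetic
check builds the nine usable drives (61 event segments, 6100 windows) at
496 Hz; the recovery experiment trains the single-stage network at
100 Hz on five subjects × six 60 s segments per seed (three seeds,
sliding stride 80), a scale at which the class structure is already
comfortably learnable; the experiment-orchestration checks use three
subjects with three clips each and one or two epochs, exercising every
stage without long optimization runs.  These sizes are the package's
choice of a small but fully representative regime for its own
verification.

## Known limitations

* The subject-based clip annotation inherits its monotone heart-rate
  assumption; it is provided for completeness and its outputs should not
  be treated as ground truth on real fear-exposure data.
* Only single-lead ECG is handled; electrodermal and respiration
  channels are out of scope.
* The per-subject discard list for partially usable drives is
  configuration, mirroring manual inspection; the package does not try
  to recover drives whose markers are broken.
* Printed real-data accuracies are not a test surface; they require the
  original PhysioNet recordings.
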