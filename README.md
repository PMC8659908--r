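# ecgstress

Real-time stress-level classification from **raw, ultra-short (3 s) ECG
windows**, for researchers and engineers building physiological-state
feedback into context-aware applications.

Acute stress shifts the autonomic balance of the heart: rate rises,
beat-to-beat variability falls. `ecgstress` exploits that signature
without computing any handcrafted heart-rate-variability features — raw
3-second windows of a single ECG lead go straight into a small 1D
convolutional network that outputs 2-level (no-stress/stress) or 3-level
(low/moderate/high) probabilities.

The core model is a single-stage CNN whose geometry is tied to the heart
period. For sampling frequency $f_s$, a window holds $3 f_s$ samples; the
convolution kernel spans $0.6\,\mathrm{s}$ ($60$ samples at 100 Hz, $300$
at 496 Hz) — one PQRST complex — and max-pooling spans
$0.8\,\mathrm{s}$ ($80$/$400$ samples) — at least one average heart
period, so the pooled response is invariant to where the R peak falls
inside a pooling window (the *peak phase difference* problem). One
convolution (32 filters), beat-period max-pooling, a 128-unit dense
layer, dropout and a softmax head give **18,339 trainable parameters** at
496 Hz — small enough for wearable edge nodes. A deeper VGG-style
five-stage network (channels 64→512, batch-norm, GAP head; 1,308,675
parameters) is provided as the higher-capacity counterpart.

Around the models sits the full data pipeline: WFDB-style record I/O and
Fourier resampling, marker-peak segmentation of seven-event driving
protocols with per-drive inclusion rules, heart-rate-based
within-subject clip annotation for fear-exposure sessions, per-subject
baseline normalization, central 5-minute truncation, 3-s fragmentation,
sliding-window training-set augmentation (stride 80 @ 100 Hz / 150 @
496 Hz), segment-level 60/20/20 splits with 4-fold cross-validation, and
a seeded synthetic ECG generator so everything runs without downloads.

## Worked example

Generate a synthetic drive, segment it by marker peaks, normalize,
truncate, window, and classify:

```r
library(ecgstress)

drv   <- generate_drive(synth_config(fs = 496), "drive06", seed = 6)
peaks <- detect_marker_peaks(drv$marker, 496)
val   <- validate_drive(peaks, drv$ecg)
val
#> <drive_validation> drive06: INCLUDE (usable marker and ECG)

subject <- subject_record_set("drive06", segment_drive(drv$ecg, peaks, val))
subject <- baseline_normalize(subject)
subject$segments <- lapply(subject$segments, truncate_central, duration_s = 300)
windows <- assemble_dataset(list(subject), n_classes = 3, fs = 496)
windows
#> <window_dataset> 700 windows of 1488 samples @496 Hz (3 s), 3 classes
#>    LOW=200  MODERATE=200  HIGH=300

model <- build_single_cnn(make_spec("SINGLE_CONV", fs = 496, n_classes = 3))
model
#> <stress_classifier> SINGLE_CONV @496 Hz, 3 classes, 18,339 trainable parameters

predict_window(model, windows$X[1, ])$probs
#>        LOW   MODERATE       HIGH
#> 0.40394... 0.50021... 0.09585...
```

The drive passes the inclusion rules (8 marker peaks, intact ECG), its 7
events yield 100 windows each after 5-minute truncation (2 low-stress
rest events, 2 moderate highway events, 3 high-stress city events), and
the untrained network already emits a normalized 3-class probability
vector for a single 1488-sample window. `train()`, `cross_validate()`
and `evaluate()` take it from there; `run_experiment(run_config(...))`
drives the whole protocol from one (JSON-loadable) configuration, and
`inst/cli/stress-ecg.R` exposes every stage as a shell command:

```sh
Rscript inst/cli/stress-ecg.R synth-drive --seed 3 --subject drive06 --out rec
Rscript inst/cli/stress-ecg.R segment-drive --record rec/drive06 --out segs.rds
Rscript inst/cli/stress-ecg.R windows --in segs.rds --fs 496 --truncate 300 --out win.rds
Rscript inst/cli/stress-ecg.R build --family single --fs 496 --classes 3
```

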