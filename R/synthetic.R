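# Synthetic stress-modulated ECG: beats are sums of five Gaussian bumps
# (P, Q, R, S, T) at fixed phase fractions of each RR interval, with the R
# wave dominant.  Stress classes separate primarily through mean heart
# rate (low 60, moderate 80, high 110 bpm by default) and secondarily
# through beat-to-beat RR variability, which is higher at rest.

#' Synthetic generator configuration
#'
#' @param fs sampling frequency in Hz.
#' @param class_hr_bpm named vector of class mean heart rates (bpm);
#'   must be strictly increasing LOW < MODERATE < HIGH.
#' @param hr_jitter_bpm standard deviation of per-beat heart-rate jitter.
#' @param rr_variability named vector of fractional RR variability per
#'   class (higher at rest, as vagal tone is withdrawn under stress).
#' @param amplitude_mv R-wave amplitude in mV.
#' @param noise_sd additive Gaussian noise standard deviation (mV).
#' @param baseline_offset_mv mean per-subject constant offset (mV).
#' @param seed default generator seed.
#' @return a `synth_config`.
#' @export
synth_config <- function(fs = 496,
                         class_hr_bpm = c(LOW = 60, MODERATE = 80, HIGH = 110),
                         hr_jitter_bpm = 2,
                         rr_variability = c(LOW = 0.10, MODERATE = 0.06, HIGH = 0.04),
                         amplitude_mv = 1.0,
                         noise_sd = 0.03,
                         baseline_offset_mv = 0,
                         seed = 1L) {
  assert_that(fs > 0, "ecgstress_config_error", "fs must be positive")
  assert_that(all(diff(class_hr_bpm[LABELS3]) > 0), "ecgstress_config_error",
              "class heart rates must be strictly increasing LOW < MODERATE < HIGH")
  assert_that(noise_sd >= 0, "ecgstress_config_error", "noise_sd must be >= 0")
  structure(list(fs = fs, class_hr_bpm = class_hr_bpm, hr_jitter_bpm = hr_jitter_bpm,
                 rr_variability = rr_variability, amplitude_mv = amplitude_mv,
                 noise_sd = noise_sd, baseline_offset_mv = baseline_offset_mv,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# PQRST template: phase offsets and widths as fractions of the local RR
# interval, amplitudes as fractions of the R amplitude.
PQRST <- list(
  offset = c(P = -0.20, Q = -0.040, R = 0, S = 0.040, T = 0.25),
  sd     = c(P = 0.035, Q = 0.012, R = 0.012, S = 0.014, T = 0.060),
  amp    = c(P = 0.15, Q = -0.15, R = 1.00, S = -0.20, T = 0.30)
)

render_beats <- function(n, fs, beat_times, rr_local, amplitude) {
  x <- numeric(n)
  for (b in seq_along(beat_times)) {
    bt <- beat_times[b]; r <- rr_local[b]
    for (w in seq_along(PQRST$offset)) {
      ctr <- bt + PQRST$offset[w] * r
      sdv <- PQRST$sd[w] * r
      a <- as.integer(max(1, floor((ctr - 4 * sdv) * fs)))
      z <- as.integer(min(n, ceiling((ctr + 4 * sdv) * fs)))
      if (a > z) next
      t <- (a:z) / fs
      x[a:z] <- x[a:z] + amplitude * PQRST$amp[w] * exp(-0.5 * ((t - ctr) / sdv)^2)
    }
  }
  x
}

#' Generate a stress-labeled synthetic ECG trace
#'
#' Beats are placed with RR intervals drawn around `60 / class_hr` with
#' per-beat jitter and class-dependent fractional variability, rendered as
#' Gaussian PQRST bumps, then additive noise and the subject offset are
#' applied.
#'
#' @param duration_s trace duration in seconds (>= 3).
#' @param config a [synth_config()].
#' @param label class label driving the heart rate (`LOW`/`MODERATE`/`HIGH`).
#' @param seed RNG seed (defaults to the config seed).
#' @param subject_id subject identity for the record.
#' @return list with `record` (an [ecg_record()]) and `truth` (a list with
#'   `beat_times` in seconds, `label` and the achieved mean heart rate).
#' @export
generate_ecg <- function(duration_s, config = synth_config(), label = "LOW",
                         seed = NULL, subject_id = "synth") {
  assert_that(duration_s >= 3, "ecgstress_bad_duration",
              "duration must be at least 3 s")
  assert_that(label %in% LABELS3, "ecgstress_unknown_event",
              sprintf("unknown label '%s'", label))
  seed <- seed %||% config$seed
  with_seed(seed, {
    hr <- config$class_hr_bpm[[label]]
    rrv <- config$rr_variability[[label]]
    beat_times <- numeric(0); rr_local <- numeric(0)
    t <- 0.4
    while (t < duration_s - 0.2) {
      hr_i <- max(20, hr + stats::rnorm(1, sd = config$hr_jitter_bpm))
      rr <- (60 / hr_i) * (1 + stats::rnorm(1, sd = rrv))
      rr <- min(2.5, max(0.25, rr))
      beat_times <- c(beat_times, t); rr_local <- c(rr_local, rr)
      t <- t + rr
    }
    n <- as.integer(round(duration_s * config$fs))
    x <- render_beats(n, config$fs, beat_times, rr_local, config$amplitude_mv)
    if (config$noise_sd > 0) x <- x + stats::rnorm(n, sd = config$noise_sd)
    x <- x + config$baseline_offset_mv
    mean_hr <- if (length(beat_times) >= 2)
      60 * (length(beat_times) - 1) / (beat_times[length(beat_times)] - beat_times[1])
      else NA_real_
    list(record = ecg_record(x, config$fs, subject_id = subject_id),
         truth = list(beat_times = beat_times, label = label, mean_hr = mean_hr))
  })
}

#' Generate a synthetic driving-protocol record
#'
#' Seven events (rest1, city1, hwy1, city2, hwy2, city3, rest2) of 5.5-7
#' minutes each, labeled rest = low, highway = moderate, city = high; a
#' 15.5 Hz marker channel carries square pulses (0.8 s wide) at the 8 event
#' boundaries.  A per-subject baseline offset is drawn around the
#' configured mean, emulating the individual bias that baseline
#' normalization removes.
#'
#' @param config a [synth_config()] (496 Hz for drives).
#' @param subject_id record name.
#' @param seed RNG seed (defaults to the config seed).
#' @param n_pulses number of marker pulses (8 for a clean drive; 7 or 9
#'   emulate the broken-marker records).
#' @return list with `ecg` (496 Hz [ecg_record()]), `marker` (15.5 Hz
#'   [marker_signal()]) and `truth` (event names, labels, boundary times
#'   in seconds, durations, subject offset).
#' @export
generate_drive <- function(config = synth_config(fs = 496), subject_id = "drive01",
                           seed = NULL, n_pulses = 8L) {
  seed <- seed %||% config$seed
  marker_fs <- 15.5
  with_seed(derive_seed(seed, "drive_plan"), {
    durations <- sample(seq(332, 420, by = 2), 7, replace = TRUE)  # even seconds
    offset <- stats::rnorm(1, config$baseline_offset_mv, 0.2)
  })
  lead <- 8; tail_s <- 8
  boundaries <- lead + c(0, cumsum(durations))        # 8 boundary times (s)
  total_s <- lead + sum(durations) + tail_s
  events <- drive_events()
  labels <- vapply(events, label_event, character(1), n_classes = 3)

  cfg <- config; cfg$baseline_offset_mv <- 0; cfg$fs <- config$fs
  pieces <- vector("list", 9)
  truth_beats <- list()
  pieces[[1]] <- generate_ecg(lead, cfg, "LOW", seed = derive_seed(seed, "lead"),
                              subject_id = subject_id)$record$samples
  for (i in seq_len(7)) {
    g <- generate_ecg(durations[i], cfg, labels[i],
                      seed = derive_seed(seed, paste0("ev", i)), subject_id = subject_id)
    pieces[[i + 1]] <- g$record$samples
    truth_beats[[events[i]]] <- g$truth$beat_times + boundaries[i]
  }
  pieces[[9]] <- generate_ecg(tail_s, cfg, "LOW", seed = derive_seed(seed, "tail"),
                              subject_id = subject_id)$record$samples
  ecg <- ecg_record(unlist(pieces) + offset, config$fs, subject_id = subject_id)

  m <- numeric(as.integer(round(total_s * marker_fs)))
  pulse_centers <- boundaries
  if (n_pulses < 8) pulse_centers <- pulse_centers[seq_len(n_pulses)]
  if (n_pulses > 8) {
    extra <- boundaries[4] + durations[4] / 2   # spurious pulse mid-event
    pulse_centers <- sort(c(pulse_centers, rep(extra, n_pulses - 8)))
  }
  half <- 0.4
  for (ctr in pulse_centers) {
    a <- max(1L, as.integer(round((ctr - half) * marker_fs)))
    z <- min(length(m), as.integer(round((ctr + half) * marker_fs)))
    m[a:z] <- 1
  }
  marker <- marker_signal(m, marker_fs, subject_id = subject_id)

  list(ecg = ecg, marker = marker,
       truth = list(events = events, labels = labels, boundaries_s = boundaries,
                    durations_s = durations, subject_offset = offset,
                    beat_times = truth_beats))
}

#' Write a synthetic drive as a WFDB-style record
#'
#' @param drive output of [generate_drive()].
#' @param path record path prefix (without extension).
#' @return the header path, invisibly.
#' @export
write_drive_wfdb <- function(drive, path) {
  write_wfdb_record(path, list(
    list(name = "ECG", samples = drive$ecg$samples, fs = drive$ecg$fs, gain = 1000),
    list(name = "marker", samples = drive$marker$samples, fs = drive$marker$fs, gain = 1000)
  ))
}

#' Generate a synthetic fear-exposure session
#'
#' A 100 Hz session of `n_clips` one-minute clips separated by 10 s
#' inter-clip gaps; per-clip heart rates cycle through the class means
#' (LOW, MODERATE, HIGH, ...), and a trigger file in the tab-separated
#' dialect records the clip intervals.
#'
#' @param config a [synth_config()] (use `fs = 100`).
#' @param n_clips number of clips (>= 3).
#' @param seed RNG seed (defaults to the config seed).
#' @param subject_id subject identifier.
#' @return list with `ecg` (100 Hz [ecg_record()]), `triggers_text`
#'   (trigger-file contents) and `truth` (per-clip labels and intervals).
#' @export
generate_spider_subject <- function(config = synth_config(fs = 100), n_clips = 6L,
                                    seed = NULL, subject_id = "subj01") {
  assert_that(n_clips >= 3, "ecgstress_bad_clip_count",
              sprintf("need at least 3 clips, got %d", n_clips))
  seed <- seed %||% config$seed
  clip_s <- 60; gap_s <- 10; lead <- 5
  labels <- rep(LABELS3, length.out = n_clips)
  offset <- with_seed(derive_seed(seed, "spider_offset"),
                      stats::rnorm(1, config$baseline_offset_mv, 0.2))
  cfg <- config; cfg$baseline_offset_mv <- 0

  pieces <- list(generate_ecg(lead, cfg, "LOW", seed = derive_seed(seed, "lead"),
                              subject_id = subject_id)$record$samples)
  starts <- numeric(n_clips)
  t <- lead
  for (i in seq_len(n_clips)) {
    starts[i] <- t
    g <- generate_ecg(clip_s, cfg, labels[i], seed = derive_seed(seed, paste0("clip", i)),
                      subject_id = subject_id)
    pieces <- c(pieces, list(g$record$samples))
    t <- t + clip_s
    if (i < n_clips) {
      pieces <- c(pieces, list(
        generate_ecg(gap_s, cfg, "LOW", seed = derive_seed(seed, paste0("gap", i)),
                     subject_id = subject_id)$record$samples))
      t <- t + gap_s
    }
  }
  ecg <- ecg_record(unlist(pieces) + offset, config$fs, subject_id = subject_id)
  clip_ids <- sprintf("clip%02d", seq_len(n_clips))
  triggers <- paste(sprintf("%s\t%g\t%g", clip_ids, starts, starts + clip_s),
                    collapse = "\n")
  list(ecg = ecg, triggers_text = triggers,
       truth = list(clip_ids = clip_ids, labels = stats::setNames(labels, clip_ids),
                    start_s = starts, end_s = starts + clip_s,
                    subject_offset = offset))
}
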