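# Clip-based fear-exposure pipeline: trigger-file parsing, heart-rate
# estimation from raw ECG spans, and subject-based 3-level annotation of
# clips from the within-subject distribution of clip heart rates.

#' Parse a clip trigger file
#'
#' One clip per line, tab-separated: `clip_id<TAB>start_s<TAB>end_s`
#' (seconds from session start).  Intervals must be valid and
#' non-overlapping within a subject.
#'
#' @param text the trigger file contents (single string or character
#'   vector of lines).
#' @return data.frame with columns `clip_id`, `start_s`, `end_s`, ordered
#'   by start time.
#' @export
parse_triggers <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  assert_that(length(lines) > 0, "ecgstress_malformed_line", "empty trigger file")
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3)
      stop_ecgstress("ecgstress_malformed_line",
                     sprintf("line %d: expected 3 tab-separated fields, got %d", i, length(f)))
    start_s <- suppressWarnings(as.numeric(f[2]))
    end_s <- suppressWarnings(as.numeric(f[3]))
    if (!is.finite(start_s) || !is.finite(end_s) || start_s < 0 || start_s >= end_s)
      stop_ecgstress("ecgstress_malformed_line",
                     sprintf("line %d: invalid interval [%s, %s]", i, f[2], f[3]))
    data.frame(clip_id = f[1], start_s = start_s, end_s = end_s,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$start_s), , drop = FALSE]
  if (nrow(out) > 1 && any(out$start_s[-1] < out$end_s[-nrow(out)]))
    stop_ecgstress("ecgstress_overlapping_clips", "clip intervals overlap")
  rownames(out) <- NULL
  out
}

#' Estimate heart rate from a raw ECG span
#'
#' Detects R peaks on the moving-average-detrended signal: candidate peaks
#' are local maxima exceeding half of a rolling maximum of the detrended
#' amplitude (evaluated on ~2 s chunks, so every chunk contains at least
#' one R peak above 30 bpm and the threshold tracks the R amplitude,
#' staying above the T wave), thinned with a 0.25 s refractory period
#' (larger peaks win).  Heart rate is `60 * (n_peaks - 1) / t`, with `t`
#' the time between the first and last detected R peak.
#'
#' @param ecg numeric vector of ECG samples, or an [ecg_record()].
#' @param fs sampling frequency in Hz (>= 100); ignored when `ecg` is an
#'   `ecg_record`.
#' @return heart rate in beats per minute.
#' @export
estimate_hr <- function(ecg, fs = NULL) {
  if (inherits(ecg, "ecg_record")) { fs <- ecg$fs; ecg <- ecg$samples }
  assert_that(!is.null(fs) && fs >= 100, "ecgstress_too_short",
              "sampling frequency must be at least 100 Hz")
  n <- length(ecg)
  assert_that(n >= 10 * fs, "ecgstress_too_short",
              "need at least a 10 s span to estimate heart rate")

  # detrend with a centered moving average spanning ~0.6 s
  w <- round(0.6 * fs); if (w %% 2 == 0) w <- w + 1
  trend <- stats::filter(ecg, rep(1 / w, w), sides = 2)
  trend[is.na(trend)] <- stats::median(ecg)
  d <- ecg - as.numeric(trend)

  # rolling maximum (adaptive R-amplitude tracker), evaluated on ~2 s chunks
  chunk <- max(1L, as.integer(round(2 * fs)))
  starts <- seq(1L, n, by = chunk)
  q <- vapply(starts, function(s) {
    max(d[s:min(n, s + chunk - 1L)])
  }, numeric(1))
  thr <- 0.5 * rep(q, each = chunk, length.out = n)

  interior <- 2:(n - 1)
  cand <- interior[d[interior] >= d[interior - 1] & d[interior] > d[interior + 1] &
                     d[interior] > thr[interior] & d[interior] > 0]
  if (length(cand) < 2)
    stop_ecgstress("ecgstress_no_beats", "no heartbeats detected in span")

  # refractory thinning: largest candidates claim a 0.25 s exclusion zone
  refr <- 0.25 * fs
  keep <- logical(length(cand))
  ord <- order(d[cand], decreasing = TRUE)
  kept_pos <- numeric(0)
  for (j in ord) {
    p <- cand[j]
    if (!length(kept_pos) || min(abs(kept_pos - p)) >= refr) {
      keep[j] <- TRUE
      kept_pos <- c(kept_pos, p)
    }
  }
  peaks <- sort(cand[keep])
  if (length(peaks) < 2)
    stop_ecgstress("ecgstress_no_beats", "fewer than two heartbeats detected")
  60 * (length(peaks) - 1) / ((peaks[length(peaks)] - peaks[1]) / fs)
}

#' Per-subject clip heart-rate profile
#'
#' @param subject_id subject identifier.
#' @param clip_hr named numeric vector: clip id -> mean heart rate in bpm.
#' @return a `subject_hr_profile` with per-clip heart rates and the
#'   subject's mean and standard deviation across clips.
#' @export
subject_hr_profile <- function(subject_id, clip_hr) {
  assert_that(length(clip_hr) > 0 && !is.null(names(clip_hr)),
              "ecgstress_too_few_clips", "clip_hr must be a named numeric vector")
  assert_that(all(clip_hr > 20 & clip_hr < 250), "ecgstress_no_beats",
              "clip heart rates outside the physiological range (20, 250) bpm")
  structure(list(subject_id = as.character(subject_id), clip_hr = clip_hr,
                 mean = mean(clip_hr), sd = stats::sd(clip_hr)),
            class = "subject_hr_profile")
}

#' Annotate clips from the subject's own heart-rate distribution
#'
#' Subject-based 3-level annotation: each clip's mean heart rate is
#' z-scored within the subject, clips are sorted ascending (stable on
#' ties), and the lowest third is labeled `LOW`, the middle third
#' `MODERATE` and the top third `HIGH` (sizes `ceiling(n/3)` for LOW and
#' MODERATE, remainder HIGH).
#'
#' @param profile a [subject_hr_profile()] with at least 3 clips and
#'   non-zero heart-rate variance.
#' @return named character vector: clip id -> label.
#' @export
annotate_clips_subject_based <- function(profile) {
  assert_that(inherits(profile, "subject_hr_profile"), "ecgstress_too_few_clips",
              "profile must be a subject_hr_profile")
  n <- length(profile$clip_hr)
  assert_that(n >= 3, "ecgstress_too_few_clips",
              sprintf("need at least 3 clips, got %d", n))
  assert_that(profile$sd > 0, "ecgstress_zero_variance",
              "all clips have identical heart rate; cannot annotate")
  z <- (profile$clip_hr - profile$mean) / profile$sd
  ord <- order(z)                     # stable for ties (radix), preserves clip order
  n_low <- ceiling(n / 3)
  n_mod <- min(ceiling(n / 3), n - n_low)
  labels <- rep("HIGH", n)
  labels[ord[seq_len(n_low)]] <- "LOW"
  if (n_mod > 0) labels[ord[n_low + seq_len(n_mod)]] <- "MODERATE"
  stats::setNames(labels, names(profile$clip_hr))
}

#' Build labeled segments for one fear-exposure subject
#'
#' Full per-subject pipeline: parse the trigger file, slice the session
#' ECG into clip spans, estimate each clip's heart rate, annotate clips
#' from the subject's own heart-rate distribution, and return the labeled
#' clip segments.
#'
#' @param ecg the session [ecg_record()] (100 Hz sessions).
#' @param triggers_text contents of the subject's trigger file.
#' @return a [subject_record_set()] of clip segments with 3-level labels.
#' @export
annotate_spider_subject <- function(ecg, triggers_text) {
  clips <- parse_triggers(triggers_text)
  spans <- lapply(seq_len(nrow(clips)), function(i) {
    a <- as.integer(round(clips$start_s[i] * ecg$fs)) + 1L
    b <- min(length(ecg$samples), as.integer(round(clips$end_s[i] * ecg$fs)))
    ecg$samples[a:b]
  })
  hr <- vapply(spans, estimate_hr, numeric(1), fs = ecg$fs)
  names(hr) <- clips$clip_id
  labels <- annotate_clips_subject_based(subject_hr_profile(ecg$subject_id, hr))
  segs <- lapply(seq_len(nrow(clips)), function(i) {
    labeled_segment(spans[[i]], ecg$fs, ecg$subject_id, clips$clip_id[i],
                    label3 = labels[[clips$clip_id[i]]])
  })
  subject_record_set(ecg$subject_id, segs)
}
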