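# Shared fixture builders; everything is generated in code at test time.

# One labeled segment of synthetic ECG.
toy_segment <- function(label = "LOW", fs = 100, duration_s = 60, seed = 1,
                        subject_id = "s1", event = "seg", config = NULL) {
  cfg <- config %||% synth_config(fs = fs)
  g <- generate_ecg(duration_s, cfg, label, seed = seed, subject_id = subject_id)
  labeled_segment(g$record$samples, fs, subject_id, event, label,
                  segment_id = paste0(subject_id, ":", event, ":", seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Balanced 3-class corpus of normalized subjects: n_subjects x n_segments
# segments of clip_s seconds at 100 Hz, labels cycling LOW/MODERATE/HIGH.
recovery_corpus <- function(seed, n_subjects = 5, n_segments = 6, clip_s = 60) {
  cfg <- synth_config(fs = 100)
  lapply(seq_len(n_subjects), function(si) {
    sid <- sprintf("s%d", si)
    segs <- lapply(seq_len(n_segments), function(ci) {
      lab <- LABELS3[(ci - 1) %% 3 + 1]
      g <- generate_ecg(clip_s, cfg, lab,
                        seed = seed * 10000 + si * 100 + ci, subject_id = sid)
      labeled_segment(g$record$samples, 100, sid, sprintf("seg%d", ci), lab)
    })
    baseline_normalize(subject_record_set(sid, segs))
  })
}

# A plain numeric labeled segment (exact arithmetic fixtures).
num_segment <- function(samples, fs = 100, label = "LOW", subject = "s1",
                        event = "ev") {
  labeled_segment(samples, fs, subject, event, label,
                  segment_id = paste0(subject, ":", event))
}
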