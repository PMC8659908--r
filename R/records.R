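# Core containers: single-lead ECG traces, low-rate marker channels,
# stress-labeled segments and per-subject segment sets.

#' ECG record container
#'
#' A uniformly sampled single-lead ECG trace together with its sampling
#' frequency and subject identity.
#'
#' @param samples numeric vector of finite sample values (ADC units or mV).
#' @param fs sampling frequency in Hz (> 0).
#' @param subject_id subject/record identifier.
#' @param channel_name channel label, e.g. `"ECG"`.
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, subject_id = "unknown", channel_name = "ECG") {
  assert_that(is.numeric(samples) && length(samples) > 0,
              "ecgstress_corrupt_record", "ECG samples must be a non-empty numeric vector")
  assert_that(all(is.finite(samples)),
              "ecgstress_corrupt_record", "ECG signal contains invalid (NaN/Inf) values")
  assert_that(is.numeric(fs) && length(fs) == 1 && fs > 0,
              "ecgstress_corrupt_record", "sampling frequency must be a positive scalar")
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs),
                 subject_id = as.character(subject_id),
                 channel_name = as.character(channel_name)),
            class = "ecg_record")
}

#' Marker signal container
#'
#' Low-rate auxiliary channel whose peaks delimit protocol events
#' (natively 15.5 Hz for driving records).
#'
#' @param samples numeric vector.
#' @param fs sampling frequency in Hz.
#' @param subject_id identity of the paired ECG record.
#' @return an object of class `marker_signal`.
#' @export
marker_signal <- function(samples, fs, subject_id = "unknown") {
  assert_that(is.numeric(samples) && length(samples) > 0,
              "ecgstress_corrupt_record", "marker samples must be a non-empty numeric vector")
  assert_that(is.numeric(fs) && length(fs) == 1 && fs > 0,
              "ecgstress_corrupt_record", "sampling frequency must be a positive scalar")
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs),
                 subject_id = as.character(subject_id)),
            class = "marker_signal")
}

#' Stress label constants
#'
#' Levels of the 3-class and 2-class stress label spaces.
#' @name stress_labels
#' @export
LABELS3 <- c("LOW", "MODERATE", "HIGH")

#' @rdname stress_labels
#' @export
LABELS2 <- c("NO_STRESS", "STRESS")

#' Labeled ECG segment
#'
#' A contiguous ECG span tagged with its protocol event and its 2- and
#' 3-class stress labels.
#'
#' @param samples numeric vector.
#' @param fs sampling frequency in Hz.
#' @param subject_id subject identifier.
#' @param event protocol event name (driving event or clip id).
#' @param label3 one of `"LOW"`, `"MODERATE"`, `"HIGH"`.
#' @param label2 one of `"NO_STRESS"`, `"STRESS"`; derived from `label3`
#'   when missing (`LOW` maps to `NO_STRESS`).
#' @param segment_id unique identifier; defaults to `subject_id:event`.
#' @return an object of class `labeled_segment`.
#' @export
labeled_segment <- function(samples, fs, subject_id, event, label3,
                            label2 = NULL, segment_id = NULL) {
  assert_that(label3 %in% LABELS3, "ecgstress_unknown_event",
              sprintf("unknown 3-class label '%s'", label3))
  if (is.null(label2)) label2 <- if (label3 == "LOW") "NO_STRESS" else "STRESS"
  assert_that(label2 %in% LABELS2, "ecgstress_unknown_event",
              sprintf("unknown 2-class label '%s'", label2))
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs),
                 subject_id = as.character(subject_id), event = as.character(event),
                 label3 = label3, label2 = label2,
                 segment_id = segment_id %||% paste0(subject_id, ":", event)),
            class = "labeled_segment")
}

#' Per-subject set of labeled segments
#'
#' Houses all labeled segments of one subject; the unit on which baseline
#' normalization operates.
#'
#' @param subject_id subject identifier.
#' @param segments list of [labeled_segment()] objects for this subject.
#' @return an object of class `subject_record_set`.
#' @export
subject_record_set <- function(subject_id, segments) {
  assert_that(length(segments) > 0, "ecgstress_empty_dataset",
              "a subject record set needs at least one segment")
  ok <- vapply(segments, inherits, logical(1), "labeled_segment")
  assert_that(all(ok), "ecgstress_empty_dataset", "segments must be labeled_segment objects")
  structure(list(subject_id = as.character(subject_id), segments = segments),
            class = "subject_record_set")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> subject=%s channel=%s fs=%g Hz n=%d (%.1f s)\n",
              x$subject_id, x$channel_name, x$fs, length(x$samples),
              length(x$samples) / x$fs))
  invisible(x)
}

#' @export
print.labeled_segment <- function(x, ...) {
  cat(sprintf("<labeled_segment> %s event=%s label3=%s label2=%s fs=%g n=%d\n",
              x$segment_id, x$event, x$label3, x$label2, x$fs, length(x$samples)))
  invisible(x)
}

#' @export
print.subject_record_set <- function(x, ...) {
  cat(sprintf("<subject_record_set> %s: %d segments (%s)\n", x$subject_id,
              length(x$segments),
              paste(vapply(x$segments, function(s) s$label3, character(1)), collapse = ", ")))
  invisible(x)
}
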