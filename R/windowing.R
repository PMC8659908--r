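# Baseline normalization, central truncation, fixed-window fragmentation,
# sliding-window augmentation and dataset assembly.

#' Subtract the low-stress baseline mean from all of a subject's segments
#'
#' The mean of the subject's low-stress (baseline) ECG is subtracted from
#' every segment of that subject, including the baseline itself, removing
#' the individual offset bias.  Idempotent: the baseline mean is zero
#' afterwards.
#'
#' @param subject a [subject_record_set()] containing at least one
#'   LOW-labeled segment.
#' @return the normalized [subject_record_set()].
#' @export
baseline_normalize <- function(subject) {
  assert_that(inherits(subject, "subject_record_set"), "ecgstress_missing_baseline",
              "input must be a subject_record_set")
  low <- vapply(subject$segments, function(s) s$label3 == "LOW", logical(1))
  assert_that(any(low), "ecgstress_missing_baseline",
              sprintf("subject %s has no LOW (baseline) segment", subject$subject_id))
  m <- mean(unlist(lapply(subject$segments[low], function(s) s$samples)))
  subject$segments <- lapply(subject$segments, function(s) {
    s$samples <- s$samples - m
    s
  })
  subject
}

#' Keep the central span of a segment
#'
#' Returns the centered `duration_s` span of a segment, discarding equal
#' margins on both sides (for an odd remainder the extra sample is dropped
#' at the end).  Used to bias the dataset equally per subject and to avoid
#' marginal noise at event borders.
#'
#' @param segment a [labeled_segment()].
#' @param duration_s target duration in seconds (default 300, i.e. 5 min).
#' @return the truncated [labeled_segment()].
#' @export
truncate_central <- function(segment, duration_s = 300) {
  need <- as.integer(round(duration_s * segment$fs))
  L <- length(segment$samples)
  assert_that(L >= need, "ecgstress_segment_too_short",
              sprintf("segment %s has %d samples; %d required for %g s",
                      segment$segment_id, L, need, duration_s))
  left <- (L - need) %/% 2L
  segment$samples <- segment$samples[(left + 1L):(left + need)]
  segment
}

new_window <- function(samples, segment, start_offset) {
  structure(list(samples = samples, fs = segment$fs,
                 label3 = segment$label3, label2 = segment$label2,
                 source_segment_id = segment$segment_id,
                 subject_id = segment$subject_id,
                 start_offset = as.integer(start_offset)),
            class = "ecg_window")
}

#' Fragment a segment into non-overlapping fixed-length windows
#'
#' Cuts `floor(L / w)` consecutive non-overlapping windows of
#' `round(window_s * fs)` samples from the segment start; the trailing
#' remainder is dropped.
#'
#' @param segment a [labeled_segment()].
#' @param window_s window length in seconds (default 3).
#' @return list of `ecg_window` objects carrying the segment's labels.
#' @export
fragment <- function(segment, window_s = 3) {
  w <- as.integer(round(window_s * segment$fs))
  L <- length(segment$samples)
  assert_that(L >= w, "ecgstress_segment_too_short",
              sprintf("segment %s shorter than one %g s window", segment$segment_id, window_s))
  k <- L %/% w
  lapply(seq_len(k), function(i) {
    off <- (i - 1L) * w
    new_window(segment$samples[(off + 1L):(off + w)], segment, off)
  })
}

#' Overlapping window crops at a fixed stride
#'
#' Training-set augmentation: windows start at offsets `0, s, 2s, ...`,
#' giving `floor((L - w) / s) + 1` crops.  At `stride = w` (and `L` a
#' multiple of `w`) this reduces to [fragment()].
#'
#' @param segment a [labeled_segment()].
#' @param window_s window length in seconds (default 3).
#' @param stride stride in samples (>= 1).
#' @return list of `ecg_window` objects.
#' @export
sliding_windows <- function(segment, window_s = 3, stride) {
  assert_that(is.numeric(stride) && length(stride) == 1 && stride >= 1 &&
                abs(stride - round(stride)) < 1e-9,
              "ecgstress_bad_stride", "stride must be a positive integer")
  stride <- as.integer(stride)
  w <- as.integer(round(window_s * segment$fs))
  L <- length(segment$samples)
  assert_that(L >= w, "ecgstress_segment_too_short",
              sprintf("segment %s shorter than one %g s window", segment$segment_id, window_s))
  starts <- seq.int(0L, L - w, by = stride)
  lapply(starts, function(off) {
    new_window(segment$samples[(off + 1L):(off + w)], segment, off)
  })
}

#' Default augmentation stride for an analysis frequency
#'
#' 80 samples at 100 Hz and 150 at 496 Hz; `round(0.8 * fs)` otherwise.
#'
#' @param fs sampling frequency in Hz.
#' @return stride in samples.
#' @export
default_stride <- function(fs) {
  if (fs == 100) 80L else if (fs == 496) 150L else as.integer(round(0.8 * fs))
}

#' Assemble a window dataset from labeled segments
#'
#' Concatenates the windows of all segments of all subjects into one
#' dataset.  Without augmentation each segment contributes its
#' non-overlapping [fragment()] windows; with augmentation, overlapping
#' [sliding_windows()] crops at the given stride.
#'
#' @param subjects list of [subject_record_set()] objects, or a flat list
#'   of [labeled_segment()] objects (already normalized and truncated).
#' @param n_classes 2 or 3.
#' @param fs expected sampling frequency; all segments must match.
#' @param augment logical; use sliding-window augmentation.
#' @param stride stride in samples (defaults to [default_stride()]).
#' @param window_s window length in seconds (default 3).
#' @return a `window_dataset`: list with matrix `X` (windows x samples),
#'   factors `y3`, `y2`, character vectors `subject` and `segment_id`,
#'   integer `offset`, plus `fs`, `n_classes`, `augmented`, `stride`,
#'   `window_s`.
#' @export
assemble_dataset <- function(subjects, n_classes = 3, fs, augment = FALSE,
                             stride = NULL, window_s = 3) {
  assert_that(n_classes %in% c(2, 3), "ecgstress_bad_class_count",
              "n_classes must be 2 or 3")
  if (inherits(subjects, "subject_record_set")) subjects <- list(subjects)
  segments <- unlist(lapply(subjects, function(s) {
    if (inherits(s, "subject_record_set")) s$segments else list(s)
  }), recursive = FALSE)
  assert_that(length(segments) > 0, "ecgstress_empty_dataset",
              "no segments to assemble")
  ok_fs <- vapply(segments, function(s) isTRUE(all.equal(s$fs, fs)), logical(1))
  assert_that(all(ok_fs), "ecgstress_spec_mismatch",
              "all segments must be sampled at the dataset frequency")
  if (augment && is.null(stride)) stride <- default_stride(fs)

  windows <- unlist(lapply(segments, function(seg) {
    if (augment) sliding_windows(seg, window_s, stride) else fragment(seg, window_s)
  }), recursive = FALSE)
  w <- as.integer(round(window_s * fs))
  X <- matrix(unlist(lapply(windows, function(x) x$samples)),
              nrow = length(windows), ncol = w, byrow = TRUE)
  structure(list(
    X = X,
    y3 = factor(vapply(windows, function(x) x$label3, character(1)), levels = LABELS3),
    y2 = factor(vapply(windows, function(x) x$label2, character(1)), levels = LABELS2),
    subject = vapply(windows, function(x) x$subject_id, character(1)),
    segment_id = vapply(windows, function(x) x$source_segment_id, character(1)),
    offset = vapply(windows, function(x) x$start_offset, integer(1)),
    fs = fs, n_classes = n_classes,
    augmented = augment, stride = if (augment) as.integer(stride) else NA_integer_,
    window_s = window_s
  ), class = "window_dataset")
}

#' Number of windows in a dataset
#' @param ds a `window_dataset`.
#' @return integer count.
#' @export
n_windows <- function(ds) nrow(ds$X)

#' Per-class window counts
#' @param ds a `window_dataset`.
#' @return named integer vector over the dataset's label space.
#' @export
class_counts <- function(ds) {
  y <- if (ds$n_classes == 3) ds$y3 else ds$y2
  table(y)
}

#' Labels of a dataset in its own class space
#' @param ds a `window_dataset`.
#' @return factor of length `n_windows(ds)`.
#' @export
dataset_labels <- function(ds) if (ds$n_classes == 3) ds$y3 else ds$y2

#' Subset a window dataset by row index or by segment ids
#'
#' @param ds a `window_dataset`.
#' @param rows integer/logical row index, or `NULL`.
#' @param segment_ids character vector of segment ids to keep, or `NULL`.
#' @return the subset `window_dataset`.
#' @export
dataset_subset <- function(ds, rows = NULL, segment_ids = NULL) {
  if (!is.null(segment_ids)) rows <- ds$segment_id %in% segment_ids
  assert_that(!is.null(rows), "ecgstress_empty_dataset", "no subset specified")
  ds$X <- ds$X[rows, , drop = FALSE]
  ds$y3 <- ds$y3[rows]; ds$y2 <- ds$y2[rows]
  ds$subject <- ds$subject[rows]; ds$segment_id <- ds$segment_id[rows]
  ds$offset <- ds$offset[rows]
  ds
}

#' @export
print.window_dataset <- function(x, ...) {
  cc <- class_counts(x)
  cat(sprintf("<window_dataset> %d windows of %d samples @%g Hz (%g s), %d classes%s\n",
              n_windows(x), ncol(x$X), x$fs, x$window_s, x$n_classes,
              if (x$augmented) sprintf(", augmented stride=%d", x$stride) else ""))
  cat("  ", paste(sprintf("%s=%d", names(cc), as.integer(cc)), collapse = "  "), "\n")
  invisible(x)
}
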