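# Driving-protocol pipeline: marker-peak detection, per-drive inclusion
# rules, event segmentation and the fixed event -> stress-label maps.

#' Driving protocol events
#'
#' The seven protocol events of a drive, in order: initial rest, three city
#' periods, two highway periods, final rest.
#'
#' @return character vector of the seven event names in protocol order.
#' @export
drive_events <- function() {
  c("rest1", "city1", "hwy1", "city2", "hwy2", "city3", "rest2")
}

#' Map a driving event to its stress label
#'
#' Rest periods are low stress, highway driving moderate, city driving
#' high; the 2-class map collapses everything but rest into `STRESS`.
#'
#' @param event one of the seven event names (see [drive_events()]).
#' @param n_classes 2 or 3.
#' @return the label string.
#' @export
label_event <- function(event, n_classes = 3) {
  assert_that(n_classes %in% c(2, 3), "ecgstress_bad_class_count",
              "n_classes must be 2 or 3")
  assert_that(length(event) == 1 && event %in% drive_events(),
              "ecgstress_unknown_event", sprintf("unknown driving event '%s'", event))
  lab3 <- switch(substr(event, 1, 4),
                 rest = "LOW", city = "HIGH", "MODERATE")
  if (n_classes == 3) lab3 else if (lab3 == "LOW") "NO_STRESS" else "STRESS"
}

#' Detect event-boundary peaks in a marker signal
#'
#' Upsamples the low-rate marker channel to the paired ECG frequency, then
#' locates its peaks: local maxima whose height exceeds half of the signal
#' range, at least 60 s apart (protocol events last minutes, so genuine
#' boundary peaks are far apart).  If the marker's extreme deviations point
#' downward the signal is negated first.
#'
#' @param marker a [marker_signal()].
#' @param fs_target target frequency in Hz (the paired ECG frequency).
#' @return integer vector of strictly increasing peak sample indices,
#'   expressed at `fs_target`.
#' @export
detect_marker_peaks <- function(marker, fs_target) {
  assert_that(inherits(marker, "marker_signal"), "ecgstress_corrupt_record",
              "marker must be a marker_signal")
  x <- resample(marker$samples, marker$fs, fs_target)
  med <- stats::median(x)
  if ((max(x) - med) < (med - min(x))) x <- -x
  rng <- max(x) - min(x)
  if (rng <= .Machine$double.eps * max(1, abs(max(x))))
    stop_ecgstress("ecgstress_no_peaks", "marker signal is flat; no peaks found")
  thr <- min(x) + 0.5 * rng
  pk <- pracma::findpeaks(x, minpeakheight = thr,
                          minpeakdistance = max(1L, as.integer(round(60 * fs_target))))
  if (is.null(pk) || nrow(pk) == 0)
    stop_ecgstress("ecgstress_no_peaks", "no marker peaks above the prominence threshold")
  sort(as.integer(pk[, 2]))
}

#' Apply the per-drive inclusion rules
#'
#' A drive is usable (`INCLUDE`) when its marker yields exactly 8
#' distinguishable peaks and the ECG channel is intact.  Drives whose
#' recorded observations say otherwise are excluded with a mirrored reason.
#' A configured per-subject discard list turns an otherwise usable drive
#' into a `PARTIAL` verdict (events dropped by manual inspection, e.g.
#' invalid signal values in the leading events).
#'
#' @param peaks integer vector of detected marker-peak indices, or `NULL`
#'   when the record provides no marker signal.
#' @param ecg the paired [ecg_record()], or `NULL` when the ECG data are
#'   missing.
#' @param subject_id subject identifier (defaults to the ECG record's).
#' @param discard_events character vector of event names to discard for
#'   this subject (configuration, not inference), or `NULL`.
#' @param notes optional recorded observation overriding detection:
#'   `"indistinct_peaks"` or `"split_record"`.
#' @return a `drive_validation` object with fields `subject_id`, `verdict`
#'   (`INCLUDE`/`PARTIAL`/`EXCLUDE`), `reason` and `discarded_events`.
#' @export
validate_drive <- function(peaks, ecg, subject_id = NULL, discard_events = NULL,
                           notes = NULL) {
  sid <- subject_id %||% (if (!is.null(ecg)) ecg$subject_id else "unknown")
  verdict <- function(v, reason, discarded = character(0)) {
    structure(list(subject_id = sid, verdict = v, reason = reason,
                   discarded_events = discarded),
              class = "drive_validation")
  }
  if (!is.null(notes) && notes == "split_record")
    return(verdict("EXCLUDE", "record is split in two parts"))
  if (is.null(peaks))
    return(verdict("EXCLUDE", "no marker signal is provided"))
  if (!is.null(notes) && notes == "indistinct_peaks")
    return(verdict("EXCLUDE", "marker peaks are not distinguishable"))
  n <- length(peaks)
  if (n < 8) return(verdict("EXCLUDE", "marker signal has less than 8 peaks"))
  if (n > 8) return(verdict("EXCLUDE", "marker signal has more than 8 peaks"))
  if (is.null(ecg) || length(ecg$samples) == 0)
    return(verdict("EXCLUDE", "missing ECG signal data"))
  if (length(discard_events) > 0) {
    bad <- setdiff(discard_events, drive_events())
    assert_that(length(bad) == 0, "ecgstress_unknown_event",
                sprintf("unknown events in discard list: %s", paste(bad, collapse = ", ")))
    return(verdict("PARTIAL",
                   sprintf("discarded %d event(s) (invalid signal values)",
                           length(discard_events)),
                   discard_events))
  }
  verdict("INCLUDE", "usable marker and ECG")
}

#' @export
print.drive_validation <- function(x, ...) {
  cat(sprintf("<drive_validation> %s: %s (%s)\n", x$subject_id, x$verdict, x$reason))
  invisible(x)
}

#' Cut a drive's ECG into labeled event segments
#'
#' The 8 marker peaks delimit 7 consecutive event segments, taken as
#' half-open intervals `[peak_i, peak_{i+1})` and labeled by protocol
#' order; events on the validation's discard list are dropped.
#'
#' @param ecg an [ecg_record()].
#' @param peaks integer vector of exactly 8 peak indices at the ECG
#'   frequency.
#' @param validation a `drive_validation` with verdict `INCLUDE` or
#'   `PARTIAL`.
#' @return list of [labeled_segment()] objects (7, minus discarded events).
#' @export
segment_drive <- function(ecg, peaks, validation) {
  assert_that(inherits(validation, "drive_validation") &&
                validation$verdict %in% c("INCLUDE", "PARTIAL"),
              "ecgstress_bad_peak_count",
              "drive was not validated as INCLUDE or PARTIAL")
  assert_that(length(peaks) == 8, "ecgstress_bad_peak_count",
              sprintf("need exactly 8 marker peaks, got %d", length(peaks)))
  peaks <- sort(as.integer(peaks))
  events <- drive_events()
  keep <- setdiff(events, validation$discarded_events)
  segs <- lapply(seq_len(7), function(i) {
    ev <- events[i]
    if (!ev %in% keep) return(NULL)
    span <- ecg$samples[peaks[i]:(peaks[i + 1] - 1L)]
    labeled_segment(span, ecg$fs, ecg$subject_id, ev,
                    label3 = label_event(ev, 3), label2 = label_event(ev, 2))
  })
  segs[!vapply(segs, is.null, logical(1))]
}

#' Recorded per-drive observations of the driving study
#'
#' The inspection notes for the 17 drives of the driving-stress study:
#' which records were usable, and why the others were not (missing marker
#' signal, wrong marker peak counts, indistinguishable peaks, missing ECG
#' data, a record split in two parts, and one drive whose first two events
#' carried invalid signal values and were discarded).
#'
#' @return a data.frame with columns `subject`, `used`
#'   (`YES`/`NO`/`PARTIALLY`) and `observation` (a category string:
#'   `ok`, `no_marker`, `more_than_8_peaks`, `indistinct_peaks`,
#'   `discard_first_two_events`, `less_than_8_peaks`, `missing_ecg`,
#'   `split_record`).
#' @export
drivedb_observations <- function() {
  data.frame(
    subject = sprintf("drive%02d", 1:17),
    used = c("NO", "NO", "NO", "NO", "PARTIALLY", "YES", "YES", "YES", "NO",
             "YES", "YES", "NO", "YES", "YES", "YES", "NO", "NO"),
    observation = c("no_marker", "more_than_8_peaks", "no_marker",
                    "indistinct_peaks", "discard_first_two_events", "ok", "ok",
                    "ok", "less_than_8_peaks", "ok", "ok", "missing_ecg", "ok",
                    "ok", "ok", "less_than_8_peaks", "split_record"),
    stringsAsFactors = FALSE
  )
}

#' Run the inclusion rules over a set of recorded observations
#'
#' Translates each recorded observation category into validation inputs
#' (peak counts, ECG presence, discard lists, notes) and applies
#' [validate_drive()], producing the per-drive inclusion report.
#'
#' @param observations a data.frame as returned by [drivedb_observations()].
#' @param discard_config named list: subject id -> character vector of
#'   events to discard for drives marked `discard_first_two_events`;
#'   defaults to dropping the first two protocol events.
#' @return a data.frame with columns `subject`, `verdict`, `reason`.
#' @export
validate_observations <- function(observations = drivedb_observations(),
                                  discard_config = NULL) {
  eight <- as.integer(round(seq(1, 8) * 6 * 60 * 496))   # nominal peak grid
  rows <- lapply(seq_len(nrow(observations)), function(i) {
    sub <- observations$subject[i]
    obs <- observations$observation[i]
    dummy_ecg <- structure(list(samples = 0, fs = 496, subject_id = sub,
                                channel_name = "ECG"), class = "ecg_record")
    v <- switch(obs,
      ok = validate_drive(eight, dummy_ecg, sub),
      no_marker = validate_drive(NULL, dummy_ecg, sub),
      more_than_8_peaks = validate_drive(c(eight, eight[8] + 300000L), dummy_ecg, sub),
      less_than_8_peaks = validate_drive(eight[1:6], dummy_ecg, sub),
      indistinct_peaks = validate_drive(eight, dummy_ecg, sub, notes = "indistinct_peaks"),
      missing_ecg = validate_drive(eight, NULL, sub),
      split_record = validate_drive(eight, dummy_ecg, sub, notes = "split_record"),
      discard_first_two_events = validate_drive(
        eight, dummy_ecg, sub,
        discard_events = (discard_config[[sub]] %||% drive_events()[1:2])),
      stop_ecgstress("ecgstress_unknown_event",
                     sprintf("unknown observation category '%s'", obs))
    )
    data.frame(subject = sub, verdict = v$verdict, reason = v$reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
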