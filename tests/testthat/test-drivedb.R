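test_that("event labels follow the fixed protocol map", {
  expected3 <- c(rest1 = "LOW", city1 = "HIGH", hwy1 = "MODERATE", city2 = "HIGH",
                 hwy2 = "MODERATE", city3 = "HIGH", rest2 = "LOW")
  for (ev in drive_events()) {
    expect_identical(label_event(ev, 3), expected3[[ev]])
    expect_identical(label_event(ev, 2),
                     if (expected3[[ev]] == "LOW") "NO_STRESS" else "STRESS")
  }
  # total and surjective onto the 3-class label space
  expect_setequal(vapply(drive_events(), label_event, character(1), n_classes = 3),
                  LABELS3)
  expect_error(label_event("lunch", 3), class = "ecgstress_unknown_event")
  expect_error(label_event("rest1", 4), class = "ecgstress_bad_class_count")
})

drv8 <- generate_drive(synth_config(fs = 496), "drive06", seed = 6)

test_that("marker peaks are recovered near the true event boundaries", {
  peaks <- detect_marker_peaks(drv8$marker, 496)
  expect_length(peaks, 8)
  expect_true(all(diff(peaks) > 0))
  expect_lt(max(abs(peaks / 496 - drv8$truth$boundaries_s)), 0.5)
})

test_that("extra marker pulses are all detected (validation is downstream)", {
  drv9 <- generate_drive(synth_config(fs = 496), "drive02", seed = 2, n_pulses = 9)
  expect_length(detect_marker_peaks(drv9$marker, 496), 9)
})

test_that("a flat marker has no peaks", {
  flat <- marker_signal(rep(0, 1000), 15.5)
  expect_error(detect_marker_peaks(flat, 496), class = "ecgstress_no_peaks")
})

test_that("inclusion verdicts mirror the recorded failure categories", {
  ecg <- drv8$ecg
  p8 <- as.integer(seq(1, 8) * 360 * 496)
  expect_identical(validate_drive(p8, ecg)$verdict, "INCLUDE")
  expect_identical(validate_drive(p8[1:6], ecg)$verdict, "EXCLUDE")
  expect_match(validate_drive(p8[1:6], ecg)$reason, "less than 8")
  expect_match(validate_drive(c(p8, p8[8] + 99000L), ecg)$reason, "more than 8")
  expect_identical(validate_drive(NULL, ecg)$verdict, "EXCLUDE")
  expect_identical(validate_drive(p8, NULL)$verdict, "EXCLUDE")
  part <- validate_drive(p8, ecg, discard_events = c("rest1", "city1"))
  expect_identical(part$verdict, "PARTIAL")
  expect_length(part$discarded_events, 2)
})

test_that("segmentation yields seven ordered labeled segments covering peak spans", {
  peaks <- detect_marker_peaks(drv8$marker, 496)
  val <- validate_drive(peaks, drv8$ecg)
  segs <- segment_drive(drv8$ecg, peaks, val)
  expect_length(segs, 7)
  expect_identical(vapply(segs, function(s) s$event, character(1)), drive_events())
  labs <- vapply(segs, function(s) s$label3, character(1))
  expect_identical(as.vector(table(factor(labs, levels = LABELS3))), c(2L, 2L, 3L))
  # half-open intervals [peak_i, peak_{i+1}): lengths sum to the peak range
  expect_identical(sum(vapply(segs, function(s) length(s$samples), integer(1))),
                   as.integer(peaks[8] - peaks[1]))
})

test_that("a partial drive drops exactly the configured events", {
  peaks <- detect_marker_peaks(drv8$marker, 496)
  val <- validate_drive(peaks, drv8$ecg, discard_events = c("rest1", "city1"))
  segs <- segment_drive(drv8$ecg, peaks, val)
  expect_length(segs, 5)
  expect_false(any(vapply(segs, function(s) s$event, character(1)) %in%
                     c("rest1", "city1")))
})

test_that("segmentation refuses a wrong peak count", {
  peaks <- detect_marker_peaks(drv8$marker, 496)
  val <- validate_drive(peaks, drv8$ecg)
  expect_error(segment_drive(drv8$ecg, peaks[1:7], val),
               class = "ecgstress_bad_peak_count")
})

test_that("the recorded observation table yields 9 usable drives", {
  obs <- drivedb_observations()
  expect_equal(nrow(obs), 17)
  rep <- validate_observations(obs)
  expect_equal(sum(rep$verdict %in% c("INCLUDE", "PARTIAL")), 9)
  expect_equal(sum(rep$verdict == "PARTIAL"), 1)
  expect_identical(rep$verdict[rep$subject == "drive05"], "PARTIAL")
  expect_identical(obs$used[rep$verdict == "INCLUDE"], rep("YES", 8))
})
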