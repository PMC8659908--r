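test_that("trigger files parse into ordered validated intervals", {
  out <- parse_triggers("clip1\t0\t60\nclip2\t70\t130")
  expect_equal(nrow(out), 2)
  expect_identical(out$clip_id, c("clip1", "clip2"))
  expect_equal(out$end_s, c(60, 130))
})

test_that("malformed and overlapping trigger lines are rejected", {
  expect_error(parse_triggers("clip1\t60\t0"), class = "ecgstress_malformed_line")
  expect_error(parse_triggers("clip1\t0"), class = "ecgstress_malformed_line")
  expect_error(parse_triggers("clip1\t0\tsixty"), class = "ecgstress_malformed_line")
  expect_error(parse_triggers("clip1\t0\t60\nclip2\t50\t110"),
               class = "ecgstress_overlapping_clips")
})

test_that("generated trigger files round-trip to the generator's ground truth", {
  sp <- generate_spider_subject(synth_config(fs = 100), n_clips = 5, seed = 9)
  out <- parse_triggers(sp$triggers_text)
  expect_identical(out$clip_id, sp$truth$clip_ids)
  expect_equal(out$start_s, sp$truth$start_s)
  expect_equal(out$end_s, sp$truth$end_s)
})

test_that("heart rate is recovered within 2 bpm of the placed beats", {
  cfg <- synth_config(fs = 100)
  for (lab in c("LOW", "HIGH")) {             # 60 and 110 bpm class means
    g <- generate_ecg(60, cfg, lab, seed = 11)
    expect_lt(abs(estimate_hr(g$record) - g$truth$mean_hr), 2)
  }
  cfg100 <- synth_config(fs = 100, class_hr_bpm = c(LOW = 60, MODERATE = 100, HIGH = 130))
  g <- generate_ecg(60, cfg100, "MODERATE", seed = 12)
  expect_lt(abs(estimate_hr(g$record) - g$truth$mean_hr), 2)
})

test_that("flat or too-short spans cannot yield a heart rate", {
  expect_error(estimate_hr(rep(0, 6000), 100), class = "ecgstress_no_beats")
  expect_error(estimate_hr(sin(1:500), 100), class = "ecgstress_too_short")
})

test_that("subject-based annotation splits clips into heart-rate tertiles", {
  p <- subject_hr_profile("s1", c(a = 60, b = 75, c = 90))
  expect_identical(unname(annotate_clips_subject_based(p)),
                   c("LOW", "MODERATE", "HIGH"))
  p6 <- subject_hr_profile("s1", c(a = 60, b = 61, c = 70, d = 71, e = 80, f = 81))
  lab <- annotate_clips_subject_based(p6)
  expect_identical(unname(lab), c("LOW", "LOW", "MODERATE", "MODERATE", "HIGH", "HIGH"))
})

test_that("degenerate clip profiles are rejected", {
  expect_error(annotate_clips_subject_based(subject_hr_profile("s", c(a = 60, b = 70))),
               class = "ecgstress_too_few_clips")
  expect_error(annotate_clips_subject_based(
    subject_hr_profile("s", c(a = 70, b = 70, c = 70))),
    class = "ecgstress_zero_variance")
})

test_that("annotation is invariant under affine transforms of the heart rates", {
  base <- c(a = 58, b = 72, c = 66, d = 95, e = 88, f = 110)
  ref <- annotate_clips_subject_based(subject_hr_profile("s", base))
  set.seed(7)
  for (i in 1:20) {
    a <- stats::runif(1, 0.2, 3); b <- stats::runif(1, -30, 30)
    # keep the transformed rates physiological; z-scores are unchanged anyway
    hr <- a * base + b
    if (any(hr <= 20 | hr >= 250)) next
    expect_identical(annotate_clips_subject_based(subject_hr_profile("s", hr)), ref)
  }
})

test_that("synthetic subjects are annotated to match generator truth", {
  agree <- vapply(1:20, function(seed) {
    sp <- generate_spider_subject(synth_config(fs = 100), n_clips = 6, seed = seed,
                                  subject_id = sprintf("subj%02d", seed))
    srs <- annotate_spider_subject(sp$ecg, sp$triggers_text)
    got <- vapply(srs$segments, function(s) s$label3, character(1))
    mean(got == unname(sp$truth$labels[vapply(srs$segments, function(s) s$event,
                                              character(1))]))
  }, numeric(1))
  expect_gte(mean(agree), 0.95)
})
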