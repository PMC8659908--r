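test_that("baseline normalization subtracts the low-stress mean from every segment", {
  s <- subject_record_set("s1", list(
    num_segment(c(1, 2, 3), label = "LOW", event = "rest"),
    num_segment(c(4, 5, 6), label = "HIGH", event = "city")))
  out <- baseline_normalize(s)
  expect_equal(out$segments[[1]]$samples, c(-1, 0, 1))
  expect_equal(out$segments[[2]]$samples, c(2, 3, 4))

  const <- subject_record_set("s2", list(
    num_segment(rep(7, 10), label = "LOW"),
    num_segment(rep(7, 10), label = "MODERATE", event = "hwy")))
  out2 <- baseline_normalize(const)
  expect_true(all(vapply(out2$segments, function(x) all(x$samples == 0), logical(1))))
})

test_that("baseline normalization matches an independent mean-subtraction oracle", {
  set.seed(3)
  segs <- lapply(seq_len(4), function(i)
    num_segment(stats::rnorm(50, mean = i), label = c("LOW", "MODERATE", "HIGH", "LOW")[i],
                event = paste0("ev", i)))
  out <- baseline_normalize(subject_record_set("s", segs))
  m <- mean(c(segs[[1]]$samples, segs[[4]]$samples))    # oracle: mean of LOW spans
  for (i in 1:4)
    expect_equal(out$segments[[i]]$samples, segs[[i]]$samples - m)
  # idempotence and zero-mean baseline
  twice <- baseline_normalize(out)
  for (i in 1:4)
    expect_equal(twice$segments[[i]]$samples, out$segments[[i]]$samples)
  expect_lt(abs(mean(c(out$segments[[1]]$samples, out$segments[[4]]$samples))), 1e-12)
})

test_that("a subject without a baseline segment cannot be normalized", {
  s <- subject_record_set("s1", list(num_segment(1:10, label = "HIGH")))
  expect_error(baseline_normalize(s), class = "ecgstress_missing_baseline")
})

test_that("central truncation keeps the centered span and drops equal margins", {
  seg <- num_segment(seq_len(36000), fs = 100)           # 6 min at 100 Hz
  out <- truncate_central(seg, 300)
  expect_length(out$samples, 30000)
  expect_identical(out$samples[1], 3001)                 # first 3000 dropped
  expect_identical(out$samples[30000], 33000)            # last 3000 dropped

  exact <- truncate_central(num_segment(seq_len(30000), fs = 100), 300)
  expect_identical(exact$samples, as.numeric(seq_len(30000)))

  # 5.12 min at 496 Hz: odd remainder, extra sample dropped at the end
  L <- 152371
  out2 <- truncate_central(num_segment(seq_len(L), fs = 496), 300)
  expect_length(out2$samples, 148800)
  expect_identical(out2$samples[1], 1786)                # left margin 1785
  expect_identical(out2$samples[148800], L - 1786)       # right margin 1786

  expect_error(truncate_central(num_segment(1:100, fs = 100), 300),
               class = "ecgstress_segment_too_short")
})

test_that("fragmentation yields floor(L/w) windows from the segment start", {
  segs <- list(
    list(seg = num_segment(stats::rnorm(30000), fs = 100), n = 100, w = 300),
    list(seg = num_segment(stats::rnorm(148800), fs = 496), n = 100, w = 1488),
    list(seg = num_segment(stats::rnorm(300), fs = 100), n = 1, w = 300))
  for (cs in segs) {
    wins <- fragment(cs$seg)
    expect_length(wins, cs$n)
    expect_true(all(vapply(wins, function(x) length(x$samples), integer(1)) == cs$w))
    expect_identical(wins[[1]]$samples, cs$seg$samples[seq_len(cs$w)])
  }
  expect_error(fragment(num_segment(1:100, fs = 100)),
               class = "ecgstress_segment_too_short")
})

test_that("sliding-window counts match the stride formula and brute force", {
  expect_length(sliding_windows(num_segment(stats::rnorm(30000), fs = 100), 3, 80), 372)
  expect_length(sliding_windows(num_segment(stats::rnorm(148800), fs = 496), 3, 150), 983)

  # property: counts agree with brute-force enumeration over random (L, w, s)
  set.seed(42)
  for (i in seq_len(1000)) {
    w <- sample(2:50, 1)
    L <- w + sample(0:200, 1)
    s <- sample(1:60, 1)
    # enumerate every legal start offset and count those on the stride grid
    brute <- sum(vapply(0:(L - w), function(o) o %% s == 0 && o + w <= L, logical(1)))
    seg <- num_segment(seq_len(L), fs = w / 3)          # window_s=3 -> w samples
    expect_length(sliding_windows(seg, 3, s), brute)
  }
})

test_that("stride-equals-window sliding is exactly fragmentation", {
  seg <- num_segment(stats::rnorm(3000), fs = 100)
  a <- fragment(seg)
  b <- sliding_windows(seg, 3, 300)
  expect_identical(lapply(a, function(x) x$samples), lapply(b, function(x) x$samples))
  expect_identical(vapply(a, function(x) x$start_offset, integer(1)),
                   vapply(b, function(x) x$start_offset, integer(1)))
})

test_that("invalid strides are rejected", {
  seg <- num_segment(stats::rnorm(600), fs = 100)
  expect_error(sliding_windows(seg, 3, 0), class = "ecgstress_bad_stride")
  expect_error(sliding_windows(seg, 3, 2.5), class = "ecgstress_bad_stride")
})

test_that("dataset assembly keeps per-class bookkeeping consistent", {
  subs <- recovery_corpus(seed = 5, n_subjects = 2, n_segments = 3, clip_s = 12)
  ds <- assemble_dataset(subs, n_classes = 3, fs = 100)
  expect_equal(sum(class_counts(ds)), n_windows(ds))
  expect_equal(n_windows(ds), 2 * 3 * 4)                # 12 s -> 4 windows each
  expect_false(ds$augmented)

  aug <- assemble_dataset(subs, n_classes = 3, fs = 100, augment = TRUE)
  expect_equal(aug$stride, 80L)                         # default stride at 100 Hz
  expect_equal(n_windows(aug), 2 * 3 * (floor((1200 - 300) / 80) + 1))
  expect_equal(sum(class_counts(aug)), n_windows(aug))

  expect_error(assemble_dataset(list(), n_classes = 3, fs = 100),
               class = "ecgstress_empty_dataset")
})
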