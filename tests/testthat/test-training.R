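test_that("the 60/20/20 split is deterministic, disjoint and exhaustive", {
  ids61 <- sprintf("seg%02d", 1:61)
  sp <- make_split(ids61, seed = 7)
  expect_length(sp$train_ids, 37)
  expect_length(sp$val_ids, 12)
  expect_length(sp$test_ids, 12)
  all_ids <- c(sp$train_ids, sp$val_ids, sp$test_ids)
  expect_setequal(all_ids, ids61)
  expect_equal(anyDuplicated(all_ids), 0)

  sp5 <- make_split(sprintf("s%d", 1:5), seed = 1)
  expect_equal(lengths(sp5[c("train_ids", "val_ids", "test_ids")]),
               c(train_ids = 3L, val_ids = 1L, test_ids = 1L))

  expect_identical(make_split(ids61, seed = 7), sp)
  expect_false(identical(make_split(ids61, seed = 8)$train_ids, sp$train_ids))
  expect_error(make_split(sprintf("s%d", 1:4), seed = 1),
               class = "ecgstress_too_few_segments")
})

test_that("fold assignment balances sizes and is reproducible", {
  ids <- sprintf("seg%02d", 1:49)
  f <- make_folds(ids, k = 4, seed = 3)
  expect_equal(sort(as.vector(table(f)), decreasing = TRUE), c(13, 12, 12, 12))
  expect_setequal(names(f), ids)
  expect_identical(make_folds(ids, k = 4, seed = 3), f)

  f4 <- make_folds(sprintf("s%d", 1:4), k = 4, seed = 1)
  expect_equal(as.vector(table(f4)), rep(1L, 4))
  expect_error(make_folds(ids, k = 1, seed = 1), class = "ecgstress_too_few_folds")
  expect_error(make_folds(sprintf("s%d", 1:3), k = 4, seed = 1),
               class = "ecgstress_too_few_segments")
})

test_that("a constant predictor's confusion matrix matches a manual tally", {
  subs <- recovery_corpus(seed = 2, n_subjects = 1, n_segments = 3, clip_s = 12)
  ds <- assemble_dataset(subs, n_classes = 3, fs = 100)    # 4 windows per class
  m <- build_single_cnn(make_spec("SINGLE_CONV", 100, 3))
  m$layers[[length(m$layers)]]$params$W[] <- 0
  m$layers[[length(m$layers)]]$params$b <- c(0, 10, 0)     # always MODERATE
  ev <- evaluate(m, ds)
  manual <- table(ds$y3)                                   # all mass in column 2
  expect_equal(ev$confusion[, "MODERATE"], as.vector(manual),
               ignore_attr = TRUE)
  expect_equal(sum(ev$confusion), n_windows(ds))
  expect_equal(ev$accuracy, manual[["MODERATE"]] / n_windows(ds))
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / sum(ev$confusion))
  expect_true(all(abs(rowSums(ev$rates) - 1) < 1e-12))
})

test_that("training on a single class reproduces it and is seed-deterministic", {
  seg <- toy_segment("HIGH", fs = 100, duration_s = 30, seed = 4, event = "city")
  srs <- subject_record_set("s1", list(
    toy_segment("LOW", fs = 100, duration_s = 30, seed = 5, event = "rest"), seg))
  srs <- baseline_normalize(srs)
  ds_all <- assemble_dataset(list(srs), n_classes = 3, fs = 100)
  ds_high <- dataset_subset(ds_all, rows = ds_all$y3 == "HIGH")

  m <- build_single_cnn(make_spec("SINGLE_CONV", 100, 3), seed = 1)
  hp <- default_hp(epochs = 5, patience = 5)
  fit1 <- train(m, ds_high, val_ds = NULL, hp = hp, seed = 11)
  ev <- evaluate(fit1$model, ds_high)
  expect_equal(ev$accuracy, 1)

  fit2 <- train(m, ds_high, val_ds = NULL, hp = hp, seed = 11)
  expect_identical(fit1$best_val_accuracy, fit2$best_val_accuracy)
  expect_identical(fit1$history, fit2$history)
})

test_that("mismatched class spaces and empty datasets are rejected", {
  subs <- recovery_corpus(seed = 6, n_subjects = 1, n_segments = 3, clip_s = 12)
  ds2 <- assemble_dataset(subs, n_classes = 2, fs = 100)
  m3 <- build_single_cnn(make_spec("SINGLE_CONV", 100, 3))
  expect_error(train(m3, ds2, NULL, default_hp(epochs = 1)),
               class = "ecgstress_class_mismatch")
  expect_error(evaluate(m3, dataset_subset(ds2, rows = rep(FALSE, n_windows(ds2)))),
               class = "ecgstress_empty_dataset")
})

test_that("augmented training windows never share segments with validation or test", {
  subs <- recovery_corpus(seed = 8, n_subjects = 2, n_segments = 3, clip_s = 12)
  base <- assemble_dataset(subs, n_classes = 3, fs = 100)
  aug <- assemble_dataset(subs, n_classes = 3, fs = 100, augment = TRUE)
  sp <- make_split(unique(base$segment_id), seed = 1)
  tr <- dataset_subset(aug, segment_ids = sp$train_ids)
  va <- dataset_subset(base, segment_ids = sp$val_ids)
  te <- dataset_subset(base, segment_ids = sp$test_ids)
  expect_length(intersect(tr$segment_id, c(va$segment_id, te$segment_id)), 0)
  # overlap can only occur within a segment, so disjoint segments imply no leakage
  expect_true(all(table(c(sp$train_ids, sp$val_ids, sp$test_ids)) == 1))
})

test_that("cross-validation reuses the fold plan and reports mean and sd", {
  subs <- recovery_corpus(seed = 9, n_subjects = 2, n_segments = 3, clip_s = 12)
  base <- assemble_dataset(subs, n_classes = 3, fs = 100)
  folds <- make_folds(unique(base$segment_id), k = 2, seed = 2)
  hp <- default_hp(epochs = 2, patience = 2)
  cv <- cross_validate(make_spec("SINGLE_CONV", 100, 3), base, folds, hp, seed = 3)
  expect_length(cv$per_fold, 2)
  expect_equal(cv$mean, mean(cv$per_fold))
  expect_match(cv$formatted, "^\\d\\.\\d{3} ± \\d\\.\\d{3}$")
  expect_error(cross_validate(make_spec("SINGLE_CONV", 100, 3), base,
                              structure(rep(1L, 6), names = unique(base$segment_id)),
                              hp),
               class = "ecgstress_too_few_folds")
})
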