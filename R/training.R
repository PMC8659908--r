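# Split/fold planning at the event-segment level, seeded training with
# early stopping, k-fold cross-validation and confusion-matrix reporting.
#
# Splits operate on segments, not windows: with sliding-window
# augmentation, window-level splits would leak near-duplicate crops
# between partitions.

#' Default training hyperparameters
#'
#' Adam with learning rate 1e-3, batches of 64, at most 50 epochs with
#' early stopping on validation accuracy (patience 10).
#'
#' @param ... overrides (`lr`, `batch_size`, `epochs`, `patience`).
#' @return named list of hyperparameters.
#' @export
default_hp <- function(...) {
  hp <- list(lr = 1e-3, batch_size = 64L, epochs = 50L, patience = 10L)
  utils::modifyList(hp, list(...))
}

#' Deterministic 60/20/20 split of segment ids
#'
#' Shuffles the segment ids under the seed, then assigns contiguous blocks
#' by ratio; validation and test sizes are `round(ratio * n)`, the
#' remainder trains.
#'
#' @param segment_ids character vector of segment ids (>= 5).
#' @param seed integer seed.
#' @param ratios train/validation/test fractions summing to 1.
#' @return a `split_plan` with `train_ids`, `val_ids`, `test_ids`.
#' @export
make_split <- function(segment_ids, seed, ratios = c(0.6, 0.2, 0.2)) {
  n <- length(segment_ids)
  assert_that(n >= 5, "ecgstress_too_few_segments",
              sprintf("need at least 5 segments to split, got %d", n))
  assert_that(abs(sum(ratios) - 1) < 1e-9, "ecgstress_config_error",
              "split ratios must sum to 1")
  shuffled <- with_seed(derive_seed(seed, "split"), sample(segment_ids))
  n_val <- round(ratios[2] * n)
  n_test <- round(ratios[3] * n)
  n_train <- n - n_val - n_test
  assert_that(n_train >= 1 && n_val >= 1 && n_test >= 1,
              "ecgstress_too_few_segments", "a partition would be empty")
  structure(list(seed = seed, ratios = ratios,
                 train_ids = shuffled[seq_len(n_train)],
                 val_ids = shuffled[n_train + seq_len(n_val)],
                 test_ids = shuffled[n_train + n_val + seq_len(n_test)]),
            class = "split_plan")
}

#' Deterministic k-fold assignment of a segment pool
#'
#' Seeded shuffle followed by round-robin assignment; fold sizes differ by
#' at most one.  Folds are segment-level and subject-agnostic: a fold can
#' contain segments of different subjects and a subject can appear in
#' several folds.
#'
#' @param pool_ids character vector of segment ids (>= k).
#' @param k number of folds (default 4).
#' @param seed integer seed.
#' @return a `fold_plan`: named integer vector segment id -> fold index.
#' @export
make_folds <- function(pool_ids, k = 4L, seed = 1L) {
  assert_that(k >= 2, "ecgstress_too_few_folds", "need at least 2 folds")
  assert_that(length(pool_ids) >= k, "ecgstress_too_few_segments",
              sprintf("need at least %d segments for %d folds", k, k))
  shuffled <- with_seed(derive_seed(seed, "folds"), sample(pool_ids))
  structure(stats::setNames(rep(seq_len(k), length.out = length(shuffled)), shuffled),
            class = "fold_plan", k = k)
}

dataset_targets <- function(ds, n_classes) {
  assert_that(ds$n_classes == n_classes, "ecgstress_class_mismatch",
              "dataset class count does not match the model")
  as.integer(if (n_classes == 3) ds$y3 else ds$y2)
}

#' Train a stress classifier
#'
#' Minimizes cross-entropy with Adam; validation accuracy is monitored
#' each epoch and the best weights are restored (early stopping).  All
#' randomness (batch shuffling, dropout) is derived from `seed`, so the
#' same inputs and seed reproduce the same history.
#'
#' @param model a `stress_classifier`.
#' @param train_ds training `window_dataset` (may be sliding-augmented).
#' @param val_ds validation `window_dataset` (non-overlapping fragments),
#'   or `NULL` to monitor training accuracy instead.
#' @param hp hyperparameters from [default_hp()].
#' @param seed integer seed.
#' @return list with `model` (best weights), `history` (per-epoch
#'   data.frame) and `best_val_accuracy`.
#' @export
train <- function(model, train_ds, val_ds = NULL, hp = default_hp(), seed = 1L) {
  assert_that(n_windows(train_ds) > 0, "ecgstress_empty_dataset", "empty training set")
  nc <- model$spec$n_classes
  assert_that(isTRUE(all.equal(train_ds$fs, model$spec$fs)), "ecgstress_class_mismatch",
              "training data frequency does not match the model")
  y_train <- dataset_targets(train_ds, nc)
  if (!is.null(val_ds)) {
    assert_that(n_windows(val_ds) > 0, "ecgstress_empty_dataset", "empty validation set")
    y_val <- dataset_targets(val_ds, nc)
  }

  layers <- model$layers
  opt <- adam_init(layers)
  n <- n_windows(train_ds)
  best <- list(acc = -Inf, layers = layers, epoch = 0L)
  history <- vector("list", hp$epochs)
  t_step <- 0L

  with_seed(derive_seed(seed, "train"), {
    for (epoch in seq_len(hp$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (s in seq(1L, n, by = hp$batch_size)) {
        idx <- ord[s:min(n, s + hp$batch_size - 1L)]
        fw <- nn_forward(layers, train_ds$X[idx, , drop = FALSE], training = TRUE)
        layers <- fw$layers
        ls <- xent_loss(fw$logits, y_train[idx], nc)
        grads <- nn_backward(layers, fw$caches, ls$dlogits)
        t_step <- t_step + 1L
        st <- adam_step(layers, grads, opt, hp$lr, t_step)
        layers <- st$layers; opt <- st$opt
        losses <- c(losses, ls$loss)
      }
      eval_model <- new_classifier(model$spec, layers)
      if (!is.null(val_ds)) {
        P <- predict_proba(eval_model, val_ds$X)
        acc <- mean(max.col(P, ties.method = "first") == y_val)
      } else {
        P <- predict_proba(eval_model, train_ds$X)
        acc <- mean(max.col(P, ties.method = "first") == y_train)
      }
      history[[epoch]] <- data.frame(epoch = epoch, train_loss = mean(losses),
                                     val_accuracy = acc)
      if (acc > best$acc) best <- list(acc = acc, layers = layers, epoch = epoch)
      if (epoch - best$epoch >= hp$patience) break
    }
  })

  list(model = new_classifier(model$spec, best$layers),
       history = do.call(rbind, history[!vapply(history, is.null, logical(1))]),
       best_val_accuracy = best$acc)
}

#' k-fold cross-validation of an architecture
#'
#' Trains one model per fold, holding the fold out for validation.  The
#' held-out fold is always drawn from the non-augmented dataset; training
#' folds are drawn from `pool_aug` when given (sliding-augmented windows
#' over the same segments), otherwise from `pool`.
#'
#' @param spec a `model_spec`.
#' @param pool non-augmented `window_dataset` over the pooled segments.
#' @param folds a `fold_plan` over the pool's segment ids.
#' @param hp hyperparameters from [default_hp()].
#' @param seed integer seed.
#' @param pool_aug optional augmented `window_dataset` over the same
#'   segment ids.
#' @return a `cv_result` with `mean`, `sd`, `per_fold` and a formatted
#'   `"mean ± sd"` string.
#' @export
cross_validate <- function(spec, pool, folds, hp = default_hp(), seed = 1L,
                           pool_aug = NULL) {
  k <- attr(folds, "k")
  assert_that(!is.null(k) && k >= 2, "ecgstress_too_few_folds",
              "folds must be a fold_plan with k >= 2")
  train_src <- pool_aug %||% pool
  accs <- vapply(seq_len(k), function(f) {
    hold_ids <- names(folds)[folds == f]
    train_ids <- names(folds)[folds != f]
    val_ds <- dataset_subset(pool, segment_ids = hold_ids)
    tr_ds <- dataset_subset(train_src, segment_ids = train_ids)
    model <- build_model(spec, seed = derive_seed(seed, paste0("fold", f)))
    train(model, tr_ds, val_ds, hp, seed = derive_seed(seed, paste0("cvtrain", f)))$best_val_accuracy
  }, numeric(1))
  structure(list(mean = mean(accs), sd = stats::sd(accs), per_fold = accs,
                 formatted = sprintf("%.3f ± %.3f", mean(accs), stats::sd(accs))),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s over %d folds\n", x$formatted, length(x$per_fold)))
  invisible(x)
}

#' Evaluate a classifier on a window dataset
#'
#' @param model a `stress_classifier`.
#' @param ds a non-empty `window_dataset` in the model's class space.
#' @return an `eval_report`: `accuracy`, `confusion` (rows true, columns
#'   predicted), `per_class_recall`, `rates` (row-normalized confusion)
#'   and `n_per_class`.
#' @export
evaluate <- function(model, ds) {
  assert_that(n_windows(ds) > 0, "ecgstress_empty_dataset", "empty evaluation set")
  nc <- model$spec$n_classes
  y <- dataset_targets(ds, nc)
  labs <- label_space(nc)
  P <- predict_proba(model, ds$X)
  pred <- max.col(P, ties.method = "first")
  conf <- table(factor(labs[y], levels = labs), factor(labs[pred], levels = labs))
  conf <- unclass(conf)
  names(dimnames(conf)) <- c("true", "predicted")
  acc <- sum(diag(conf)) / sum(conf)
  recall <- diag(conf) / pmax(1, rowSums(conf))
  rates <- conf / pmax(1, rowSums(conf))
  structure(list(accuracy = acc, confusion = conf, per_class_recall = recall,
                 rates = rates, n_per_class = rowSums(conf)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.2f%% over %d windows\n",
              100 * x$accuracy, sum(x$confusion)))
  print(x$confusion)
  invisible(x)
}
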