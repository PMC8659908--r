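# Run configuration and end-to-end experiment orchestration:
# ingest -> annotate -> normalize -> window -> split -> cross-validate ->
# final training -> test evaluation, one report row per configuration.

#' Build a run configuration
#'
#' @param fs analysis frequency in Hz (100 or 496).
#' @param n_classes 2 or 3.
#' @param families architectures to run (default both).
#' @param window_s window length in seconds.
#' @param stride augmentation stride in samples (default 80 at 100 Hz,
#'   150 at 496 Hz).
#' @param augment logical vector of augmentation settings to run.
#' @param ratios train/validation/test fractions (must sum to 1).
#' @param k cross-validation folds.
#' @param seed master seed for every random stage.
#' @param epochs,batch_size,lr,patience training hyperparameters.
#' @param dataset corpus kind: `"drive"` (496 Hz protocol records,
#'   downsampled when `fs = 100`) or `"spider"` (100 Hz clip sessions).
#' @param n_subjects synthetic subjects to generate.
#' @param n_clips clips per subject (spider corpus).
#' @param truncate_s central truncation of event segments in seconds
#'   (drive corpus; `NULL` disables).
#' @param paths optional named list; `segments` may point to an RDS file
#'   holding a list of [subject_record_set()] objects to use instead of
#'   synthetic data.
#' @return a `run_config`.
#' @export
run_config <- function(fs = 496, n_classes = 3,
                       families = c("SINGLE_CONV", "VGG_INSPIRED"),
                       window_s = 3, stride = NULL, augment = TRUE,
                       ratios = c(0.6, 0.2, 0.2), k = 4L, seed = 1L,
                       epochs = 50L, batch_size = 64L, lr = 1e-3, patience = 10L,
                       dataset = c("drive", "spider"), n_subjects = 9L,
                       n_clips = 6L, truncate_s = 300, paths = list()) {
  dataset <- match.arg(dataset)
  assert_that(abs(sum(ratios) - 1) < 1e-9, "ecgstress_config_error",
              "split ratios must sum to 1")
  assert_that(all(families %in% c("SINGLE_CONV", "VGG_INSPIRED")),
              "ecgstress_config_error", "unknown architecture family")
  assert_that(n_classes %in% c(2, 3), "ecgstress_config_error",
              "n_classes must be 2 or 3")
  if (is.null(stride)) stride <- default_stride(fs)
  structure(list(fs = fs, n_classes = n_classes, families = families,
                 window_s = window_s, stride = as.integer(stride),
                 augment = as.logical(augment), ratios = ratios, k = as.integer(k),
                 seed = as.integer(seed), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 patience = as.integer(patience), dataset = dataset,
                 n_subjects = as.integer(n_subjects), n_clips = as.integer(n_clips),
                 truncate_s = truncate_s, paths = paths),
            class = "run_config")
}

#' Load a run configuration from JSON
#' @param path JSON file path.
#' @return a `run_config`.
#' @export
run_config_from_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  assert_that(length(unknown) == 0, "ecgstress_config_error",
              sprintf("unknown config fields: %s", paste(unknown, collapse = ", ")))
  do.call(run_config, raw)
}

#' Segment a drive record into labeled event segments
#'
#' Convenience pipeline over one record: detect marker peaks at the ECG
#' frequency, apply the inclusion rules, then cut and label the event
#' segments.
#'
#' @param ecg an [ecg_record()].
#' @param marker the paired [marker_signal()].
#' @param discard_events optional configured discard list for this subject.
#' @return a [subject_record_set()]; errors with the validation reason if
#'   the drive is excluded.
#' @export
segment_drive_record <- function(ecg, marker, discard_events = NULL) {
  peaks <- detect_marker_peaks(marker, ecg$fs)
  val <- validate_drive(peaks, ecg, discard_events = discard_events)
  assert_that(val$verdict %in% c("INCLUDE", "PARTIAL"), "ecgstress_bad_peak_count",
              sprintf("drive %s excluded: %s", val$subject_id, val$reason))
  subject_record_set(ecg$subject_id, segment_drive(ecg, peaks, val))
}

resample_segment <- function(seg, fs_out) {
  seg$samples <- resample(seg$samples, seg$fs, fs_out)
  seg$fs <- fs_out
  seg
}

build_synthetic_corpus <- function(config) {
  seed <- config$seed
  if (config$dataset == "drive") {
    subjects <- lapply(seq_len(config$n_subjects), function(i) {
      sid <- sprintf("drive%02d", i)
      cfg <- synth_config(fs = 496)
      drv <- generate_drive(cfg, subject_id = sid, seed = derive_seed(seed, paste0("drv", i)))
      segment_drive_record(drv$ecg, drv$marker)
    })
    if (config$fs == 100) {
      subjects <- lapply(subjects, function(s) {
        s$segments <- lapply(s$segments, resample_segment, fs_out = 100)
        s
      })
    }
    subjects
  } else {
    lapply(seq_len(config$n_subjects), function(i) {
      sid <- sprintf("subj%02d", i)
      cfg <- synth_config(fs = 100)
      sp <- generate_spider_subject(cfg, n_clips = config$n_clips,
                                    seed = derive_seed(seed, paste0("spi", i)),
                                    subject_id = sid)
      annotate_spider_subject(sp$ecg, sp$triggers_text)
    })
  }
}

#' Run a full experiment from a configuration
#'
#' Generates (or loads) the corpus, baseline-normalizes each subject,
#' truncates event segments, splits segments 60/20/20, cross-validates
#' each requested configuration (architecture x augmentation) over the
#' train+validation pool, trains a final model per configuration and
#' evaluates it on the held-out test segments.  Fully deterministic under
#' the configured seed.
#'
#' @param config a [run_config()].
#' @return an `experiment_report`: data.frame `report` with one row per
#'   configuration (`family`, `augment`, `cv_accuracy`, `cv_sd`,
#'   `cv_formatted`, `test_accuracy`) plus `split`, `folds` and the
#'   per-configuration `eval_reports`.
#' @export
run_experiment <- function(config) {
  assert_that(inherits(config, "run_config"), "ecgstress_config_error",
              "config must be a run_config")
  subjects <- if (!is.null(config$paths$segments))
    readRDS(config$paths$segments) else build_synthetic_corpus(config)

  subjects <- lapply(subjects, baseline_normalize)
  if (config$dataset == "drive" && !is.null(config$truncate_s)) {
    subjects <- lapply(subjects, function(s) {
      s$segments <- lapply(s$segments, truncate_central, duration_s = config$truncate_s)
      s
    })
  }

  base_ds <- assemble_dataset(subjects, n_classes = config$n_classes, fs = config$fs,
                              augment = FALSE, window_s = config$window_s)
  aug_ds <- if (any(config$augment))
    assemble_dataset(subjects, n_classes = config$n_classes, fs = config$fs,
                     augment = TRUE, stride = config$stride,
                     window_s = config$window_s) else NULL

  ids <- unique(base_ds$segment_id)
  split <- make_split(ids, config$seed, config$ratios)
  pool_ids <- c(split$train_ids, split$val_ids)
  folds <- make_folds(pool_ids, k = config$k, seed = config$seed)
  hp <- default_hp(lr = config$lr, batch_size = config$batch_size,
                   epochs = config$epochs, patience = config$patience)

  rows <- list(); reports <- list()
  for (family in config$families) {
    for (aug in config$augment) {
      spec <- make_spec(family, config$fs, config$n_classes)
      tag <- sprintf("%s_sw%s", family, if (aug) "on" else "off")
      pool_base <- dataset_subset(base_ds, segment_ids = pool_ids)
      pool_aug <- if (aug) dataset_subset(aug_ds, segment_ids = pool_ids) else NULL
      cv <- cross_validate(spec, pool_base, folds, hp,
                           seed = derive_seed(config$seed, tag), pool_aug = pool_aug)

      train_src <- if (aug) aug_ds else base_ds
      model <- build_model(spec, seed = derive_seed(config$seed, paste0(tag, "_final")))
      fit <- train(model,
                   dataset_subset(train_src, segment_ids = split$train_ids),
                   dataset_subset(base_ds, segment_ids = split$val_ids),
                   hp, seed = derive_seed(config$seed, paste0(tag, "_fit")))
      ev <- evaluate(fit$model, dataset_subset(base_ds, segment_ids = split$test_ids))

      rows[[tag]] <- data.frame(frequency = config$fs, family = family, augment = aug,
                                n_classes = config$n_classes,
                                cv_accuracy = cv$mean, cv_sd = cv$sd,
                                cv_formatted = cv$formatted,
                                test_accuracy = ev$accuracy,
                                stringsAsFactors = FALSE)
      reports[[tag]] <- ev
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(list(report = report, split = split, folds = folds,
                 eval_reports = reports, config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  df <- x$report
  df$cv_accuracy <- NULL; df$cv_sd <- NULL
  df$test_accuracy <- sprintf("%.2f%%", 100 * df$test_accuracy)
  print(df, row.names = FALSE)
  invisible(x)
}
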