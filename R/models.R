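# The two stress-classification architectures.  Both consume raw 3 s ECG
# windows; kernel and pooling lengths of the single-stage network are tied
# to the sampling frequency so that pooling spans roughly one average
# heartbeat (0.8 s) and the kernel one beat complex (0.6 s).

#' Label space for a class count
#' @param n_classes 2 or 3.
#' @return character vector of labels.
#' @export
label_space <- function(n_classes) {
  assert_that(n_classes %in% c(2, 3), "ecgstress_bad_class_count",
              "n_classes must be 2 or 3")
  if (n_classes == 3) LABELS3 else LABELS2
}

#' Build a model specification
#'
#' Populates the frequency-dependent hyperparameters: at 100 Hz the kernel
#' spans 60 samples (0.6 s, one PQRST complex) and the pooling 80 samples
#' (0.8 s, one average heartbeat); at 496 Hz they become 300 and 400.  For
#' any other frequency the same 0.6 s / 0.8 s spans are used.  Windows are
#' 3 s, i.e. `round(3 * fs)` samples.
#'
#' @param family `"SINGLE_CONV"` or `"VGG_INSPIRED"`.
#' @param fs sampling frequency in Hz.
#' @param n_classes 2 or 3.
#' @param n_filters convolution filters of the single-stage net (default 32).
#' @param hidden_units hidden dense width of the single-stage net (default 128).
#' @param dropout_rate dropout fraction (default 0.5).
#' @return a `model_spec`.
#' @export
make_spec <- function(family = c("SINGLE_CONV", "VGG_INSPIRED"), fs, n_classes,
                      n_filters = 32L, hidden_units = 128L, dropout_rate = 0.5) {
  family <- match.arg(family)
  assert_that(is.numeric(fs) && fs > 0, "ecgstress_spec_mismatch",
              "fs must be positive")
  assert_that(n_classes %in% c(2, 3), "ecgstress_bad_class_count",
              "n_classes must be 2 or 3")
  kp <- if (fs == 100) c(60L, 80L) else if (fs == 496) c(300L, 400L)
        else c(as.integer(round(0.6 * fs)), as.integer(round(0.8 * fs)))
  structure(list(
    family = family, fs = fs, window_len = as.integer(round(3 * fs)),
    n_classes = as.integer(n_classes),
    kernel_len = kp[1], pool_len = kp[2],
    n_filters = as.integer(n_filters), hidden_units = as.integer(hidden_units),
    stage_channels = c(64L, 128L, 256L, 512L, 512L),
    dropout_rate = dropout_rate
  ), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s @%g Hz: window=%d kernel=%d pool=%d classes=%d\n",
              x$family, x$fs, x$window_len, x$kernel_len, x$pool_len, x$n_classes))
  invisible(x)
}

new_classifier <- function(spec, layers) {
  structure(list(spec = spec, layers = layers), class = "stress_classifier")
}

#' Build the single-stage 1D CNN
#'
#' One valid (unpadded) convolutional stage whose kernel spans a beat
#' complex, max-pooling over roughly one heart period (stride equal to the
#' pooling length), leaky-ReLU activation, then two fully connected layers
#' with dropout between them and a softmax head.
#'
#' @param spec a `model_spec` with family `SINGLE_CONV`.
#' @param seed RNG seed for weight initialization (default 1).
#' @return a `stress_classifier`.
#' @export
build_single_cnn <- function(spec, seed = 1L) {
  assert_that(inherits(spec, "model_spec") && spec$family == "SINGLE_CONV",
              "ecgstress_spec_mismatch", "spec family must be SINGLE_CONV")
  conv_out <- spec$window_len - spec$kernel_len + 1L
  assert_that(conv_out >= spec$pool_len, "ecgstress_spec_mismatch",
              "window too short for one pooling span after convolution")
  pooled <- conv_out %/% spec$pool_len
  layers <- with_seed(derive_seed(seed, "single_cnn"), list(
    layer_conv1d(spec$kernel_len, 1L, spec$n_filters, pad = 0L),
    layer_maxpool(spec$pool_len),
    layer_lrelu(),
    layer_flatten(),
    layer_dense(pooled * spec$n_filters, spec$hidden_units),
    layer_lrelu(),
    layer_dropout(spec$dropout_rate),
    layer_dense(spec$hidden_units, spec$n_classes)
  ))
  new_classifier(spec, layers)
}

#' Build the VGG-inspired 1D CNN
#'
#' Five stages of (same-padded convolution, batch normalization,
#' leaky-ReLU, max-pooling of size 2, dropout) with channel widths
#' doubling from 64 to 512, followed by global average pooling and a
#' dense softmax head.
#'
#' @param spec a `model_spec` with family `VGG_INSPIRED`.
#' @param seed RNG seed for weight initialization (default 1).
#' @return a `stress_classifier`.
#' @export
build_vgg_cnn <- function(spec, seed = 1L) {
  assert_that(inherits(spec, "model_spec") && spec$family == "VGG_INSPIRED",
              "ecgstress_spec_mismatch", "spec family must be VGG_INSPIRED")
  assert_that(spec$window_len >= 2L^5L, "ecgstress_input_too_short",
              "input must survive 5 halvings; need at least 32 samples")
  chans <- spec$stage_channels
  layers <- with_seed(derive_seed(seed, "vgg_cnn"), {
    out <- list()
    c_in <- 1L
    for (ci in chans) {
      out <- c(out, list(
        layer_conv1d(3L, c_in, ci, pad = 1L),
        layer_batchnorm(ci),
        layer_lrelu(),
        layer_maxpool(2L),
        layer_dropout(spec$dropout_rate)
      ))
      c_in <- ci
    }
    c(out, list(layer_gap(), layer_dense(chans[length(chans)], spec$n_classes)))
  })
  new_classifier(spec, layers)
}

#' Build a classifier from its spec
#' @param spec a `model_spec`.
#' @param seed RNG seed for weight initialization.
#' @return a `stress_classifier`.
#' @export
build_model <- function(spec, seed = 1L) {
  if (spec$family == "SINGLE_CONV") build_single_cnn(spec, seed)
  else build_vgg_cnn(spec, seed)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars: convolution and dense weights and
#' biases plus batch-norm affine terms (running statistics excluded).
#'
#' @param model a `stress_classifier`.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$layers, function(ly) {
    sum(vapply(ly$params, length, numeric(1)), 0)
  }, numeric(1)))
}

#' Class probabilities for a batch of windows
#'
#' Inference mode: dropout disabled, batch normalization using running
#' statistics.  Deterministic for fixed weights and inputs.
#'
#' @param model a `stress_classifier`.
#' @param X matrix (windows x samples) with `spec$window_len` columns.
#' @param batch_size forward batch size.
#' @return matrix (windows x classes) of probabilities, columns in
#'   [label_space()] order.
#' @export
predict_proba <- function(model, X, batch_size = 256L) {
  assert_that(ncol(X) == model$spec$window_len, "ecgstress_length_mismatch",
              sprintf("windows have %d samples; model expects %d",
                      ncol(X), model$spec$window_len))
  n <- nrow(X)
  P <- matrix(0, n, model$spec$n_classes)
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(n, s + batch_size - 1L)
    P[idx, ] <- softmax(nn_forward(model$layers, X[idx, , drop = FALSE],
                                   training = FALSE)$logits)
  }
  colnames(P) <- label_space(model$spec$n_classes)
  P
}

#' Classify a single window
#'
#' @param model a `stress_classifier`.
#' @param window numeric vector of length `spec$window_len`, or an
#'   `ecg_window`.
#' @return list with `label` (argmax; ties resolved to the lowest class
#'   index) and `probs` (named probability vector).
#' @export
predict_window <- function(model, window) {
  if (inherits(window, "ecg_window")) window <- window$samples
  assert_that(length(window) == model$spec$window_len, "ecgstress_length_mismatch",
              sprintf("window has %d samples; model expects %d",
                      length(window), model$spec$window_len))
  p <- predict_proba(model, matrix(window, 1))[1, ]
  list(label = names(p)[which.max(p)], probs = p)
}

#' Post-pooling feature map of the single-stage network
#'
#' Runs only the convolution and max-pooling layers, exposing the pooled
#' feature map (positions x filters) used to study phase invariance of the
#' beat-spanning pooling.
#'
#' @param model a `SINGLE_CONV` `stress_classifier`.
#' @param window numeric vector of length `spec$window_len`.
#' @return matrix (pooled positions x filters).
#' @export
conv_pool_features <- function(model, window) {
  assert_that(model$spec$family == "SINGLE_CONV", "ecgstress_spec_mismatch",
              "pooled features are defined for the single-stage network")
  assert_that(length(window) == model$spec$window_len, "ecgstress_length_mismatch",
              "window length mismatch")
  x <- array(window, c(1L, length(window), 1L))
  for (ly in model$layers[1:2]) x <- forward_layer(ly, x, training = FALSE)$out
  matrix(x, dim(x)[2], dim(x)[3])
}

#' @export
print.stress_classifier <- function(x, ...) {
  cat(sprintf("<stress_classifier> %s @%g Hz, %d classes, %s trainable parameters\n",
              x$spec$family, x$spec$fs, x$spec$n_classes,
              format(count_parameters(x), big.mark = ",")))
  for (ly in x$layers) {
    np <- sum(vapply(ly$params, length, numeric(1)), 0)
    cat(sprintf("  %-10s %s\n", ly$type,
                if (np > 0) sprintf("params=%d", np) else ""))
  }
  invisible(x)
}
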