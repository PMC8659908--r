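test_that("spec constants are tied to the sampling frequency", {
  s496 <- make_spec("SINGLE_CONV", 496, 3)
  expect_equal(s496$kernel_len, 300)
  expect_equal(s496$pool_len, 400)
  expect_equal(s496$window_len, 1488)

  s100 <- make_spec("SINGLE_CONV", 100, 3)
  expect_equal(s100$kernel_len, 60)
  expect_equal(s100$pool_len, 80)
  expect_equal(s100$window_len, 300)

  v <- make_spec("VGG_INSPIRED", 496, 2)
  expect_equal(v$stage_channels, c(64L, 128L, 256L, 512L, 512L))

  # other frequencies keep the 0.6 s / 0.8 s beat spans
  s256 <- make_spec("SINGLE_CONV", 256, 3)
  expect_equal(s256$kernel_len, round(0.6 * 256))
  expect_equal(s256$pool_len, round(0.8 * 256))

  expect_error(make_spec("SINGLE_CONV", 100, 5), class = "ecgstress_bad_class_count")
})

# Independent layerwise parameter-count oracle for the single-stage net.
single_cnn_param_oracle <- function(spec) {
  conv_out <- spec$window_len - spec$kernel_len + 1
  pooled <- conv_out %/% spec$pool_len
  conv <- (spec$kernel_len * 1 + 1) * spec$n_filters
  fc1 <- pooled * spec$n_filters * spec$hidden_units + spec$hidden_units
  fc2 <- spec$hidden_units * spec$n_classes + spec$n_classes
  conv + fc1 + fc2
}

# Independent oracle for the 5-stage net: conv weights+biases, batch-norm
# affine pairs, and the dense head after global average pooling.
vgg_param_oracle <- function(spec) {
  ch <- c(1, spec$stage_channels)
  conv <- sum(3 * ch[-length(ch)] * ch[-1] + ch[-1])
  bn <- 2 * sum(spec$stage_channels)
  head <- spec$stage_channels[5] * spec$n_classes + spec$n_classes
  conv + bn + head
}

test_that("parameter counts match independent layerwise formulas and stay in budget", {
  s496 <- make_spec("SINGLE_CONV", 496, 3)
  m496 <- build_single_cnn(s496)
  expect_equal(count_parameters(m496), single_cnn_param_oracle(s496))
  expect_equal(count_parameters(m496), 18339)
  expect_lte(count_parameters(m496), 28866)

  s100 <- make_spec("SINGLE_CONV", 100, 3)
  m100 <- build_single_cnn(s100)
  expect_equal(count_parameters(m100), single_cnn_param_oracle(s100))
  expect_equal(count_parameters(m100), 14755)

  vs <- make_spec("VGG_INSPIRED", 496, 3)
  vm <- build_vgg_cnn(vs)
  expect_equal(count_parameters(vm), vgg_param_oracle(vs))
  expect_equal(count_parameters(vm), 1308675)
  expect_lte(count_parameters(vm), 1554819)

  # 2-class heads shrink only the final layer
  expect_equal(count_parameters(build_single_cnn(make_spec("SINGLE_CONV", 496, 2))),
               18339 - 129)
})

test_that("both architectures emit normalized probability vectors", {
  set.seed(1)
  for (model in list(build_single_cnn(make_spec("SINGLE_CONV", 100, 3)),
                     build_vgg_cnn(make_spec("VGG_INSPIRED", 100, 2)))) {
    w <- stats::rnorm(model$spec$window_len)
    p <- predict_window(model, w)$probs
    expect_length(p, model$spec$n_classes)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-9)
    # inference is deterministic (dropout off, running batch-norm stats)
    expect_identical(p, predict_window(model, w)$probs)
  }
})

test_that("an all-zero head yields uniform probabilities with lowest-index argmax", {
  m <- build_single_cnn(make_spec("SINGLE_CONV", 100, 3))
  m$layers[[length(m$layers)]]$params$W[] <- 0
  m$layers[[length(m$layers)]]$params$b[] <- 0
  out <- predict_window(m, stats::rnorm(300))
  expect_equal(unname(out$probs), rep(1 / 3, 3))
  expect_identical(out$label, "LOW")
})

test_that("windows of the wrong length are rejected", {
  m <- build_single_cnn(make_spec("SINGLE_CONV", 100, 3))
  expect_error(predict_window(m, stats::rnorm(299)), class = "ecgstress_length_mismatch")
  expect_error(predict_proba(m, matrix(0, 2, 100)), class = "ecgstress_length_mismatch")
})

test_that("the 5-stage network needs inputs that survive five halvings", {
  spec <- make_spec("VGG_INSPIRED", 10, 3)   # 30-sample window < 2^5
  expect_error(build_vgg_cnn(spec), class = "ecgstress_input_too_short")
})

test_that("argmax is stable under small constant input shifts", {
  m <- build_single_cnn(make_spec("SINGLE_CONV", 100, 3), seed = 2)
  set.seed(21)
  for (i in 1:10) {
    w <- stats::rnorm(300, sd = 0.5)
    base <- predict_window(m, w)$label
    expect_identical(predict_window(m, w + 0.01)$label, base)
    expect_identical(predict_window(m, w - 0.01)$label, base)
  }
})
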