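test_that("analytic parameter audit matches per-layer hand counts", {
  audit <- count_trainable_parameters(mbeegnet_spec())
  expect_equal(audit$total, 8908L)
  expect_equal(audit$total, sum(audit$entries$count))

  # first branch (F1 = 4, KE = 16) contributes 472 before the shared dense
  b1 <- audit$entries[grepl("^branch1_", audit$entries$layer), ]
  expect_equal(sum(b1$count), 472L)
  expect_equal(sort(b1$count), sort(c(64L, 8L, 176L, 16L, 128L, 64L, 16L)))
  expect_equal(sum(b1$count),
               eegnet_branch_param_oracle(4, 16, n_ch = 22))

  # dense layer: concatenated 56 maps x 17 time points -> 4 classes
  dense <- audit$entries[audit$entries$layer %in% c("dense", "dense_bias"), ]
  expect_equal(sum(dense$count), 952L * 4L + 4L)
})

test_that("audit equals brute-force enumeration of the built model's tensors", {
  for (spec in list(mbeegnet_spec(), eegnet_spec(),
                    shallow_spec(), mb_shallow_spec(),
                    mbeegnet_spec(n_channels = 44, n_classes = 3))) {
    audit <- count_trainable_parameters(spec)
    m <- build_model(spec, seed = 5)
    tensors <- model_parameter_tensors(m)
    expect_equal(sum(tensors$count), audit$total)
    # per-layer agreement: batch-norm scale+shift pairs sum to the audit row
    grp <- sub("_(scale|shift)$", "", tensors$tensor)
    by_layer <- tapply(tensors$count, grp, sum)
    for (nm in names(by_layer)) {
      expect_equal(unname(by_layer[[nm]]),
                   audit$entries$count[audit$entries$layer == nm],
                   info = nm)
    }
  }
})

test_that("a model with a single dense layer counts weights plus bias", {
  # smallest expressible network: one branch collapsing to a 10-wide flatten
  spec <- multibranch_spec(
    list(eegnet_branch(1L, 2L, 0, depth_multiplier = 1L,
                       pointwise_filters = 1L,
                       separable_kernel_length = 2L,
                       pool_lengths = c(4L, 4L))),
    n_channels = 2L, n_samples = 160L, n_classes = 4L)
  audit <- count_trainable_parameters(spec)
  dense <- audit$entries[audit$entries$layer %in% c("dense", "dense_bias"), ]
  expect_equal(sum(dense$count), 10L * 4L + 4L)
})

test_that("multiplication counter reproduces the flattened-filter argument", {
  expect_equal(conv_multiplication_count(10, c(8, 1, 1), 100), 8000L)
  expect_equal(conv_multiplication_count(10, c(1, 22, 1), 21), 4620L)
  expect_equal(conv_multiplication_count(10, c(8, 22, 3), 100), 528000L)
  expect_equal(conv_multiplication_count(10, c(8, 1, 1), 100) +
                 conv_multiplication_count(10, c(1, 22, 1), 21), 12620L)
  expect_error(conv_multiplication_count(0, c(8, 1, 1), 100), "positive")
  expect_error(conv_multiplication_count(10, c(8, -1, 1), 100), "positive")
})

test_that("model summaries are deterministic with the documented shapes", {
  spec <- mbeegnet_spec()
  s1 <- describe_model(spec)
  s2 <- describe_model(spec)
  expect_identical(s1, s2)
  expect_equal(attr(s1, "total"), 8908L)
  # flattened length per branch is F2 x 17 (floor(floor(1125/8)/8) = 17)
  expect_equal(s1$output_shape[s1$layer == "branch1_flatten"], "(136)")  # 8*17
  expect_equal(s1$output_shape[s1$layer == "branch3_flatten"], "(544)")  # 32*17
  expect_true("concatenate" %in% s1$layer)

  # single-branch summary lists no concatenation layer
  s3 <- describe_model(eegnet_spec())
  expect_false("concatenate" %in% s3$layer)

  # shallow branch KE=25 with pool 75/15: pooled time length 69
  s4 <- describe_model(shallow_spec())
  expect_equal(s4$output_shape[s4$layer == "branch1_avgpool"], "(40, 1, 69)")
})

test_that("spec validation rejects impossible geometries", {
  expect_error(multibranch_spec(list(), 22, 1125, 4), "at least one")
  expect_error(
    multibranch_spec(list(eegnet_branch(4, 2000, 0)), 22, 1125, 4),
    "kernel_length")
  expect_error(
    multibranch_spec(list(eegnet_branch(4, 16, 0), shallow_branch(40, 25)),
                     22, 1125, 4),
    "family")
  expect_error(eegnet_branch(4, 16, dropout_rate = 1), "dropout")
  expect_error(
    build_model(multibranch_spec(list(eegnet_branch(4, 16, 0,
                                                    pool_lengths = c(64, 64))),
                                 22, 1125, 4)),
    "time axis")
})

test_that("one-branch multibranch equals the single-branch builder structurally", {
  br <- eegnet_branch(8L, 32L, 0.1)
  a <- multibranch_spec(list(br), 22, 1125, 4)
  b <- eegnet_spec(branch = br)
  expect_identical(describe_model(a), describe_model(b))
  expect_identical(model_parameter_tensors(build_model(a, seed = 3)),
                   model_parameter_tensors(build_model(b, seed = 3)))
})

test_that("softmax output is a probability vector for any input", {
  spec <- multibranch_spec(list(eegnet_branch(2, 8, 0)), 4, 160, 4)
  m <- build_model(spec, seed = 2)
  x <- tiny_epochs(n = 7, n_ch = 4, n_s = 160, n_cls = 4)
  p <- predict(m, x)
  expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-6)
  expect_true(all(p >= 0))
})

test_that("permuting the dense class weights permutes the probabilities", {
  spec <- multibranch_spec(list(eegnet_branch(2, 8, 0)), 4, 160, 4)
  m <- build_model(spec, seed = 2)
  x <- tiny_epochs(n = 5, n_ch = 4, n_s = 160, n_cls = 4)
  p <- predict(m, x)
  perm <- c(3, 1, 4, 2)
  w <- model_weights(m)
  w$dense <- w$dense[, perm, drop = FALSE]
  w$dense_bias <- w$dense_bias[perm, , drop = FALSE]
  m2 <- build_model(spec, seed = 2)
  set_model_weights(m2, w)
  p2 <- predict(m2, x)
  expect_equal(unname(p2), unname(p[, perm]), tolerance = 1e-6)
})

test_that("inference is deterministic and batch-size invariant", {
  spec <- multibranch_spec(list(eegnet_branch(4, 16, 0.2)), 6, 320, 4)
  m <- build_model(spec, seed = 9)
  x <- tiny_epochs(n = 9, n_ch = 6, n_s = 320, n_cls = 4)
  p1 <- predict(m, x)
  p2 <- predict(m, x)
  expect_identical(p1, p2)          # dropout off in inference
  single <- do.call(rbind, lapply(seq_len(9), function(i) {
    predict(m, subset_epochs(x, i))
  }))
  expect_equal(unname(single), unname(p1), tolerance = 1e-5)
})
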