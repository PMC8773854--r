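test_that("window arithmetic gives the canonical epoch lengths", {
  rec <- matrix(rnorm(2 * 3000), 2, 3000)
  ep <- extract_epochs(rec, fs = 250, cue_times = c(2, 6),
                       window = window_spec(0.5, 4.5))
  expect_equal(n_samples(ep), 1125)          # 250 * 4.5
  expect_equal(n_trials(ep), 2)

  ep2 <- extract_epochs(matrix(0, 1, 5000), fs = 500, cue_times = 2,
                        window = window_spec(0.5, 4.5))
  expect_equal(n_samples(ep2), 2250)         # linear in fs

  # epoch k starts at round(fs * (cue_k - pre_cue)) with half-open windows
  rec3 <- matrix(seq_len(100), 1, 100)
  ep3 <- extract_epochs(rec3, fs = 10, cue_times = 2,
                        window = window_spec(0.5, 1.0))
  expect_equal(as.vector(ep3$data[1, 1, ]), 16:25)  # 0-based start 15

  expect_error(
    extract_epochs(rec, fs = 250, cue_times = 0.2,
                   window = window_spec(0.5, 4.5)),
    "trial")
  expect_error(window_spec(pre_cue_s = 2, total_s = 1), "pre_cue_s")
})

test_that("standardization: fitted stats, degenerate channels, composition", {
  # hand-computable: values {0, 2} on one channel -> mean 1, sd 1
  x <- epoch_set(array(c(0, 2, 5, 5), c(2, 2, 1)), labels = c(0L, 1L),
                 fs = 10, class_names = c("a", "b"))
  expect_warning(st <- fit_standardization(x), "constant")
  expect_equal(unname(st$mean), c(1, 5))
  expect_equal(unname(st$sd[1]), 1)
  expect_true(st$degenerate[2])

  z <- apply_standardization(x, st)
  expect_equal(as.vector(z$data[, 1, ]), c(-1, 1))
  expect_equal(as.vector(z$data[, 2, ]), c(0, 0))  # degenerate -> zeros
  expect_identical(z$labels, x$labels)

  # Monte-Carlo: a standard-normal channel recovers mean 0 / sd 1 within 3 SE
  n <- 1e5
  big <- withr::with_seed(11, epoch_set(array(rnorm(n), c(10, 1, n / 10)),
                                        labels = rep(0L, 10), fs = 100))
  st2 <- fit_standardization(big)
  expect_lt(abs(st2$mean[1]), 3 / sqrt(n))
  expect_lt(abs(st2$sd[1] - 1), 3 / sqrt(2 * n))

  # applying stats fitted on the same set standardizes it exactly
  y <- tiny_epochs(n = 6, n_ch = 4, n_s = 50)
  ys <- apply_standardization(y, fit_standardization(y))
  for (ch in 1:4) {
    v <- as.vector(ys$data[, ch, ])
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-6)
  }

  # identity stats leave the data untouched
  id <- structure(list(mean = rep(0, 4), sd = rep(1, 4),
                       degenerate = rep(FALSE, 4),
                       channel_names = y$channel_names),
                  class = "standardization_stats")
  expect_equal(apply_standardization(y, id)$data, y$data)
  expect_error(apply_standardization(tiny_epochs(n_ch = 3), st), "channels")
})

test_that("resampling halves 500 Hz epochs to 1125 samples and keeps tones", {
  t_s <- (0:2249) / 500
  x <- epoch_set(array(rep(sin(2 * pi * 10 * t_s), each = 1), c(1, 1, 2250)),
                 labels = 0L, fs = 500)
  y <- resample_epochs(x, 250)
  expect_equal(n_samples(y), 1125)
  expect_equal(y$fs, 250)
  expect_equal(fft_peak_hz(y$data[1, 1, ], 250), 10, tolerance = 0.1)
  # energy of the tone (well below the new Nyquist) preserved within 1%
  expect_equal(mean(y$data[1, 1, 100:1000]^2), mean(x$data[1, 1, 200:2000]^2),
               tolerance = 0.01)

  expect_identical(resample_epochs(x, 500), x)   # same-rate identity
  expect_error(resample_epochs(x, 0), "target_fs")
})

test_that("channel selection reorders, slices and validates names", {
  x <- tiny_epochs(n = 3, n_ch = 5, n_s = 20)
  same <- select_channels(x, x$channel_names)
  expect_equal(same$data, x$data)

  sub <- select_channels(x, c("ch4", "ch2"))
  expect_equal(dim(sub$data), c(3, 2, 20))
  expect_equal(sub$channel_names, c("ch4", "ch2"))
  expect_equal(sub$data[, 1, ], x$data[, 4, ])

  expect_error(select_channels(x, c("ch1", "nope", "zap")), "nope")

  # high-density montage reduction: 128 -> 44 channels
  big <- tiny_epochs(n = 2, n_ch = 128, n_s = 10)
  keep <- paste0("ch", seq(2, 88, by = 2))
  expect_equal(dim(select_channels(big, keep)$data), c(2, 44, 10))
})
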