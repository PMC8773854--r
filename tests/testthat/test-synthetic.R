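test_that("generator geometry, balance and determinism", {
  spec <- synth_spec(n_trials_per_class = 10, seed = 5)
  x <- generate_epochs(spec)
  expect_equal(dim(x$data), c(40, 22, 1125))
  expect_equal(x$fs, 250)
  expect_equal(as.vector(table(x$labels)), rep(10L, 4))

  y <- generate_epochs(synth_spec(n_trials_per_class = 10, seed = 5))
  expect_identical(x$data, y$data)
  z <- generate_epochs(synth_spec(n_trials_per_class = 10, seed = 6))
  expect_false(identical(x$data, z$data))
})

test_that("spec validation rejects unphysical signatures", {
  expect_error(synth_spec(snr = 0), "snr")
  sig <- list(a = tibble::tibble(channel = 1, freq = 200, amplitude = 1))
  expect_error(synth_spec(fs = 250, class_signatures = sig), "Nyquist")
  sig2 <- list(a = tibble::tibble(channel = 30, freq = 10, amplitude = 1))
  expect_error(synth_spec(n_channels = 22, class_signatures = sig2),
               "channels")
})

test_that("class trials carry their spectral peak on signature channels", {
  spec <- synth_spec(n_trials_per_class = 3, snr = 5, seed = 2)
  x <- generate_epochs(spec)
  sigs <- spec$class_signatures
  for (cls in seq_along(sigs)) {
    trial <- which(x$labels == cls - 1L)[1]
    row <- sigs[[cls]][1, ]
    expect_equal(fft_peak_hz(x$data[trial, row$channel, ], x$fs),
                 row$freq, tolerance = 0.3)
  }
  # a non-signature channel shows no such dominant line
  free_ch <- setdiff(seq_len(22), unlist(purrr::map(sigs, "channel")))[1]
  sp <- abs(fft(x$data[1, free_ch, ]))^2
  expect_lt(max(sp[2:562]) / sum(sp[2:562]), 0.2)
})

test_that("background noise follows the requested 1/f^alpha slope", {
  for (alpha in c(0.5, 1)) {
    spec <- synth_spec(n_trials_per_class = 5, snr = 1e-6,
                       noise_exponent = alpha, seed = 9)
    x <- generate_epochs(spec)
    n <- n_samples(x)
    freqs <- seq_len(n %/% 2) * x$fs / n
    keep <- freqs >= 1 & freqs <= 100
    # average periodogram over trials and channels, slope on log-log axes
    psd <- 0
    for (i in 1:5) for (ch in c(1, 5, 9)) {
      sp <- abs(fft(x$data[i, ch, ]))^2
      psd <- psd + sp[2:(n %/% 2 + 1)]
    }
    fit <- stats::lm(log(psd[keep]) ~ log(freqs[keep]))
    expect_equal(unname(coef(fit)[2]), -alpha, tolerance = 0.2)
  }
})

test_that("band-power reference classifier calibrates the generator", {
  tr <- generate_epochs(synth_spec(n_trials_per_class = 20, snr = 2, seed = 1))
  te <- generate_epochs(synth_spec(n_trials_per_class = 15, snr = 2, seed = 2))
  res <- bandpower_reference_classifier(tr, te)
  expect_gte(res$accuracy, 0.9)

  # train == test on (nearly) noiseless data is perfect
  clean <- generate_epochs(synth_spec(n_trials_per_class = 5, snr = 50,
                                      seed = 3))
  expect_equal(bandpower_reference_classifier(clean, clean)$accuracy, 1.0)

  expect_error(
    bandpower_reference_classifier(tr, te, bands = list(c(100, 130))),
    "Nyquist")
})

test_that("reference accuracy rises monotonically with snr (seed-averaged)", {
  snrs <- c(0.1, 0.5, 1, 2, 5)
  acc <- sapply(snrs, function(s) {
    mean(sapply(1:2, function(sd) {
      tr <- generate_epochs(synth_spec(n_trials_per_class = 12, snr = s,
                                       seed = sd))
      te <- generate_epochs(synth_spec(n_trials_per_class = 12, snr = s,
                                       seed = sd + 50))
      bandpower_reference_classifier(tr, te)$accuracy
    }))
  })
  expect_true(all(diff(acc) >= 0))
  expect_lt(acc[1], acc[5])
})

test_that("published benchmark tables load with the expected layout", {
  bci <- reference_results("bciiv2a")
  expect_equal(nrow(bci), 36)
  expect_setequal(unique(bci$model),
                  c("eegnet", "mbeegnet", "shallowconvnet",
                    "mb_shallowconvnet"))
  hgd <- reference_results("hgd")
  expect_equal(nrow(hgd), 56)
  expect_equal(sum(is.na(hgd$accuracy)), 0)
  summ <- reference_summary()
  expect_equal(summ$mean_accuracy[summ$model == "mbeegnet"], 82.01)
})
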