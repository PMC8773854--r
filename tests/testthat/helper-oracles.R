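# Shared helpers: small fixtures and independent oracles used across tests.

# tiny labelled epoch set with reproducible contents
tiny_epochs <- function(n = 8, n_ch = 3, n_s = 40, n_cls = 2, fs = 100,
                        seed = 1) {
  withr::with_seed(seed, {
    epoch_set(array(rnorm(n * n_ch * n_s), c(n, n_ch, n_s)),
              labels = rep(seq_len(n_cls) - 1L, length.out = n),
              fs = fs,
              class_names = paste0("c", seq_len(n_cls)))
  })
}

# brute-force Cohen's kappa: expand the confusion matrix back into label
# vectors and count agreement / chance agreement from first principles
kappa_bruteforce <- function(cm) {
  k <- nrow(cm)
  yt <- rep(rep(seq_len(k), k), times = as.vector(t(cm)))
  yp <- rep(rep(seq_len(k), each = k), times = as.vector(t(cm)))
  n <- length(yt)
  po <- sum(yt == yp) / n
  pe <- 0
  for (cls in seq_len(k)) {
    pe <- pe + (sum(yt == cls) / n) * (sum(yp == cls) / n)
  }
  (po - pe) / (1 - pe)
}

# per-layer hand count of one EEGNet-style branch (convention: bias-free
# convolutions, 2 trainable parameters per batch-norm map)
eegnet_branch_param_oracle <- function(f1, ke, n_ch, d = 2, f2 = d * f1,
                                       sep = 16) {
  m <- f1 * d
  ke * f1 + 2 * f1 + n_ch * m + 2 * m + sep * m + m * f2 + 2 * f2
}

expect_epochs_equal <- function(a, b, tol = 0) {
  expect_equal(dim(a$data), dim(b$data))
  if (tol == 0) expect_identical(a$data, b$data)
  else expect_equal(a$data, b$data, tolerance = tol)
  expect_identical(a$labels, b$labels)
  expect_identical(a$fs, b$fs)
  expect_identical(a$channel_names, b$channel_names)
  expect_identical(a$class_names, b$class_names)
}

# dominant nonzero frequency of a signal, in Hz (periodogram argmax)
fft_peak_hz <- function(x, fs) {
  n <- length(x)
  sp <- abs(fft(x))^2
  freqs <- (seq_len(n) - 1) * fs / n
  half <- 2:(n %/% 2)
  freqs[half][which.max(sp[half])]
}
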