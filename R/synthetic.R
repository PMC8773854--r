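#' Default motor-imagery class signatures
#'
#' Four classes in the spirit of the standard cue-based MI paradigm (left
#' hand, right hand, feet, tongue): each class adds a band-limited
#' oscillation — lateralized mu (10 Hz) over the contralateral hand area,
#' beta (20 Hz) over midline/fronto-central sites — on a class-specific,
#' disjoint channel subset. This gives a learner both spectral and spatial
#' structure to exploit, which is exactly what temporal-then-spatial
#' convolutions are built to pick up.
#'
#' @param n_channels montage size (default 22); signature channels are
#'   placed relative to it.
#' @return named list (one element per class) of tibbles with columns
#'   `channel` (1-based), `freq` (Hz), `amplitude` (relative).
#' @export
mi_class_signatures <- function(n_channels = 22L) {
  if (n_channels < 12L) {
    abort("default signatures need at least 12 channels; supply your own below that")
  }
  third <- n_channels %/% 3L
  list(
    left_hand  = tibble(channel = (2L * third):(2L * third + 2L),
                        freq = 10, amplitude = 1),
    right_hand = tibble(channel = (third - 2L):third, freq = 10, amplitude = 1),
    feet       = tibble(channel = (third + 2L):(third + 4L), freq = 20,
                        amplitude = 1),
    tongue     = tibble(channel = (n_channels - 3L):(n_channels - 1L),
                        freq = 20, amplitude = 1))
}

#' Synthetic motor-imagery EEG specification
#'
#' Describes a balanced, labelled set of MI-like epochs: class-dependent
#' band-limited oscillations (random phase per trial) on class-specific
#' channels, superimposed on 1/f^alpha background noise, at the standard
#' 22 channels x 1125 samples (4.5 s at 250 Hz) geometry. `snr` is the
#' amplitude (RMS) ratio of an amplitude-1 signature oscillation to the
#' per-channel background noise; the generator is fully determined by
#' `seed`.
#'
#' @param n_trials_per_class trials generated per class.
#' @param n_channels number of channels (default 22).
#' @param fs sampling rate in Hz (default 250).
#' @param duration_s epoch length in seconds (default 4.5).
#' @param class_signatures named list of per-class signature tibbles
#'   (`channel`, `freq`, `amplitude`); default [mi_class_signatures()].
#' @param noise_exponent spectral exponent alpha of the background
#'   (default 1, i.e. pink noise).
#' @param snr signal-to-noise amplitude ratio (> 0; default 2, a clearly
#'   separable regime meant for testing pipelines, not for realism).
#' @param seed integer seed.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_trials_per_class = 10L, n_channels = 22L, fs = 250,
                       duration_s = 4.5,
                       class_signatures = mi_class_signatures(n_channels),
                       noise_exponent = 1, snr = 2, seed = 1L) {
  if (snr <= 0) abort("`snr` must be > 0")
  if (n_trials_per_class < 1L) abort("`n_trials_per_class` must be >= 1")
  for (nm in names(class_signatures)) {
    sig <- class_signatures[[nm]]
    if (any(sig$freq >= fs / 2)) {
      abort(sprintf("class '%s' has signature frequencies at or above Nyquist", nm))
    }
    if (any(sig$channel < 1L | sig$channel > n_channels)) {
      abort(sprintf("class '%s' has signature channels outside 1..%d",
                    nm, n_channels))
    }
  }
  structure(list(n_trials_per_class = as.integer(n_trials_per_class),
                 n_channels = as.integer(n_channels), fs = fs,
                 duration_s = duration_s, class_signatures = class_signatures,
                 noise_exponent = noise_exponent, snr = snr,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# one epoch of 1/f^alpha noise, unit RMS per channel, via spectral shaping
pink_noise <- function(n_channels, n, fs, alpha) {
  freqs <- seq_len(n %/% 2) * fs / n
  scale <- freqs^(-alpha / 2)
  out <- matrix(0, n_channels, n)
  for (c in seq_len(n_channels)) {
    spec <- complex(real = rnorm(length(freqs)),
                    imaginary = rnorm(length(freqs))) * scale
    nf <- length(freqs)
    full <- complex(length.out = n)
    full[2:(nf + 1L)] <- spec
    # Hermitian symmetry for a real signal (Nyquist bin made real)
    if (n %% 2 == 0) full[nf + 1L] <- complex(real = Re(spec[nf]))
    full[n + 2L - (2:(nf + 1L))] <- Conj(full[2:(nf + 1L)])
    x <- Re(fft(full, inverse = TRUE)) / n
    out[c, ] <- x / sqrt(mean(x^2))
  }
  out
}

#' Generate a synthetic labelled epoch set
#'
#' Draws `n_classes * n_trials_per_class` epochs (balanced, class-blocked
#' order): each trial is per-channel unit-RMS 1/f^alpha noise plus the
#' trial's class oscillations with uniformly random phase, scaled by
#' `snr * amplitude`. Identical seeds give identical arrays.
#'
#' @param spec a [synth_spec()].
#' @return an `epoch_set` of shape
#'   `(n_classes * n_trials_per_class, n_channels, round(fs * duration_s))`.
#' @examples
#' x <- generate_epochs(synth_spec(n_trials_per_class = 5, seed = 42))
#' dim(x$data)  # 20 x 22 x 1125
#' @export
generate_epochs <- function(spec) {
  if (!inherits(spec, "synth_spec")) abort("`spec` must be a synth_spec")
  n <- as.integer(round(spec$fs * spec$duration_s))
  k <- length(spec$class_signatures)
  n_tot <- k * spec$n_trials_per_class
  t_sec <- (seq_len(n) - 1L) / spec$fs
  withr::with_seed(spec$seed, {
    data <- array(0, c(n_tot, spec$n_channels, n))
    labels <- integer(n_tot)
    i <- 0L
    for (cls in seq_len(k)) {
      sig <- spec$class_signatures[[cls]]
      for (tr in seq_len(spec$n_trials_per_class)) {
        i <- i + 1L
        labels[i] <- cls - 1L
        x <- pink_noise(spec$n_channels, n, spec$fs, spec$noise_exponent)
        for (row in seq_len(nrow(sig))) {
          phase <- runif(1, 0, 2 * pi)
          osc <- sqrt(2) * sin(2 * pi * sig$freq[row] * t_sec + phase)
          ch <- sig$channel[row]
          x[ch, ] <- x[ch, ] + spec$snr * sig$amplitude[row] * osc
        }
        data[i, , ] <- x
      }
    }
    epoch_set(data, labels, spec$fs,
              class_names = names(spec$class_signatures))
  })
}

#' Band-power nearest-centroid reference classifier
#'
#' A deliberately simple non-neural baseline in the band-power tradition:
#' for every trial, the log band power of each (channel, band) pair is
#' computed from the periodogram, class centroids are fitted on the
#' training set, and test trials are assigned to the nearest centroid
#' (Euclidean). Deterministic; serves to calibrate the synthetic
#' generator's separability and as a floor for the networks.
#'
#' @param train,test `epoch_set`s with matching geometry.
#' @param bands named list of `c(low, high)` frequency edges in Hz
#'   (default mu 8-12 Hz and beta 18-22 Hz); edges must be below Nyquist.
#' @param channels optional channel indices to restrict the features to.
#' @return a list with `accuracy`, `predictions` (integer 0-based) and
#'   `confusion` (an `mbeeg_cm`).
#' @export
bandpower_reference_classifier <- function(train, test,
                                           bands = list(mu = c(8, 12),
                                                        beta = c(18, 22)),
                                           channels = NULL) {
  validate_epoch_set(train); validate_epoch_set(test)
  for (b in bands) {
    if (max(b) >= train$fs / 2) abort("band edges must be below Nyquist")
  }
  channels <- channels %||% seq_len(n_channels(train))
  feat <- function(x) {
    n <- n_samples(x)
    freqs <- seq_len(n %/% 2) * x$fs / n
    idx <- purrr::map(bands, ~which(freqs >= .x[1] & freqs <= .x[2]))
    out <- matrix(0, n_trials(x), length(channels) * length(bands))
    for (i in seq_len(n_trials(x))) {
      col <- 0L
      for (ch in channels) {
        sp <- abs(fft(x$data[i, ch, ]))^2
        sp <- sp[2:(n %/% 2 + 1L)]  # drop DC
        for (j in seq_along(bands)) {
          col <- col + 1L
          out[i, col] <- log(mean(sp[idx[[j]]]) + 1e-12)
        }
      }
    }
    out
  }
  ftr <- feat(train)
  fte <- feat(test)
  k <- length(train$class_names)
  centroids <- t(vapply(0:(k - 1L),
                        function(cls) colMeans(ftr[train$labels == cls, , drop = FALSE]),
                        numeric(ncol(ftr))))
  d2 <- outer(rowSums(fte^2), rep(1, k)) - 2 * fte %*% t(centroids) +
    outer(rep(1, nrow(fte)), rowSums(centroids^2))
  pred <- max.col(-d2, ties.method = "first") - 1L
  cm <- confusion_matrix(test$labels, pred, k, class_names = test$class_names)
  list(accuracy = mean(pred == test$labels), predictions = pred,
       confusion = cm)
}
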