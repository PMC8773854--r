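#' Cue-locked extraction window
#'
#' Describes the fixed-length window cut around each cue: the window starts
#' `pre_cue_s` seconds before the cue and lasts `total_s` seconds, so the
#' default (0.5 s pre-cue, 4.5 s total) covers `[cue - 0.5, cue + 4.0]`
#' seconds — 1125 samples at 250 Hz. Sample indexing is 0-based and windows
#' are half-open `[start, start + N)`.
#'
#' @param pre_cue_s seconds of signal kept before the cue (default 0.5).
#' @param total_s total window length in seconds (default 4.5).
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(pre_cue_s = 0.5, total_s = 4.5) {
  if (total_s <= 0) abort("`total_s` must be > 0")
  if (pre_cue_s < 0) abort("`pre_cue_s` must be >= 0")
  if (pre_cue_s >= total_s) abort("`pre_cue_s` must be smaller than `total_s`")
  structure(list(pre_cue_s = pre_cue_s, total_s = total_s),
            class = "window_spec")
}

#' Extract fixed-length epochs from a continuous recording
#'
#' Cuts one epoch per cue from a continuous multichannel recording. Epoch
#' `k` starts at sample `round(fs * (cue_k - pre_cue_s))` and has exactly
#' `round(fs * total_s)` samples, so 4.5 s at 250 Hz always yields 1125
#' samples. A window that would fall outside the recording raises a range
#' error naming the offending trial.
#'
#' @param recording numeric matrix `n_channels x n_samples` of continuous
#'   signal.
#' @param fs sampling rate in Hz.
#' @param cue_times numeric vector of cue onsets in seconds.
#' @param window a [window_spec()].
#' @param labels integer vector of 0-based class labels, one per cue
#'   (defaults to all 0).
#' @param channel_names,class_names,subject_id metadata forwarded to
#'   [epoch_set()].
#' @return an `epoch_set` with `length(cue_times)` trials.
#' @examples
#' rec <- matrix(rnorm(3 * 2000), 3, 2000)
#' ep <- extract_epochs(rec, fs = 250, cue_times = c(1.0, 4.0),
#'                      window = window_spec(0.5, 2.0))
#' n_samples(ep)  # 500
#' @export
extract_epochs <- function(recording, fs, cue_times, window = window_spec(),
                           labels = NULL, channel_names = NULL,
                           class_names = NULL, subject_id = NULL) {
  if (!is.matrix(recording)) abort("`recording` must be a channels x samples matrix")
  n_ch <- nrow(recording)
  n_total <- ncol(recording)
  n_len <- as.integer(round(fs * window$total_s))
  if (is.null(labels)) labels <- rep(0L, length(cue_times))
  starts <- as.integer(round(fs * (cue_times - window$pre_cue_s)))  # 0-based
  bad <- which(starts < 0L | starts + n_len > n_total)
  if (length(bad)) {
    abort(sprintf(
      "epoch window out of recording bounds for trial(s) %s",
      paste(bad, collapse = ", ")))
  }
  data <- array(0, c(length(cue_times), n_ch, n_len))
  for (k in seq_along(cue_times)) {
    data[k, , ] <- recording[, (starts[k] + 1L):(starts[k] + n_len), drop = FALSE]
  }
  epoch_set(data, labels, fs,
            channel_names = channel_names %||% rownames(recording),
            class_names = class_names, subject_id = subject_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit per-channel standardization statistics
#'
#' Computes each channel's mean and standard deviation over all trials and
#' samples of the (training) set. Statistics should be fitted on the
#' training session only and then applied to both sessions, which avoids
#' leaking test-set scale into training. Channels whose standard deviation
#' is below `1e-12` are flagged degenerate (with a warning) and later map
#' to all-zero output rather than dividing by zero.
#'
#' @param train an `epoch_set` with at least one trial.
#' @return an object of class `standardization_stats` with fields `mean`,
#'   `sd`, `degenerate` (logical per channel) and `channel_names`.
#' @export
fit_standardization <- function(train) {
  validate_epoch_set(train)
  if (n_trials(train) == 0L) abort("`train` must contain at least one trial")
  m <- apply(train$data, 2, mean)
  # population-style sd over the pooled trials x samples axis: {0, 2} -> 1
  s <- sqrt(apply(train$data, 2, function(v) mean((v - mean(v))^2)))
  degenerate <- s < 1e-12
  if (any(degenerate)) {
    warn(sprintf("channel(s) %s are (near-)constant; standardized output will be zero",
                 paste(train$channel_names[degenerate], collapse = ", ")))
  }
  structure(list(mean = m, sd = s, degenerate = degenerate,
                 channel_names = train$channel_names),
            class = "standardization_stats")
}

#' Apply per-channel standardization
#'
#' Transforms every channel as `(x - mean_c) / sd_c` with statistics from
#' [fit_standardization()]. Metadata, shape and labels are unchanged.
#' Degenerate channels (flagged at fit time) are set to zero.
#'
#' @param epochs an `epoch_set`.
#' @param stats a `standardization_stats` object with matching channel count.
#' @return a standardized `epoch_set`.
#' @export
apply_standardization <- function(epochs, stats) {
  validate_epoch_set(epochs)
  if (length(stats$mean) != n_channels(epochs)) {
    abort(sprintf("`stats` has %d channels but `epochs` has %d",
                  length(stats$mean), n_channels(epochs)))
  }
  data <- epochs$data
  for (c in seq_len(n_channels(epochs))) {
    if (stats$degenerate[c]) {
      data[, c, ] <- 0
    } else {
      data[, c, ] <- (data[, c, ] - stats$mean[c]) / stats$sd[c]
    }
  }
  epoch_set(data, epochs$labels, epochs$fs, epochs$channel_names,
            epochs$class_names, epochs$subject_id)
}

#' Resample all epochs to a new sampling rate
#'
#' Polyphase (anti-aliased) resampling of every channel of every trial via
#' [signal::resample()]. The sample count scales by `target_fs / fs`
#' (2250 samples at 500 Hz become 1125 at 250 Hz) and spectral content
#' below the new Nyquist frequency is preserved. Both down- and
#' up-sampling are allowed.
#'
#' @param epochs an `epoch_set`.
#' @param target_fs target sampling rate in Hz (positive).
#' @param filter_order half-order of the anti-aliasing/interpolation
#'   filter (default 16; the default of [signal::resample()] is cheaper
#'   but leaves visible passband ripple).
#' @return an `epoch_set` at `target_fs`.
#' @export
resample_epochs <- function(epochs, target_fs, filter_order = 16L) {
  validate_epoch_set(epochs)
  if (!is.finite(target_fs) || target_fs <= 0) {
    abort("`target_fs` must be > 0")
  }
  if (target_fs == epochs$fs) return(epochs)
  frac <- ratio_approx(target_fs / epochs$fs)
  p <- frac[1]; q <- frac[2]
  n_in <- n_samples(epochs)
  n_out <- as.integer(ceiling(n_in * p / q))
  out <- array(0, c(n_trials(epochs), n_channels(epochs), n_out))
  for (i in seq_len(n_trials(epochs))) {
    for (c in seq_len(n_channels(epochs))) {
      out[i, c, ] <- signal::resample(epochs$data[i, c, ], p, q,
                                      d = filter_order)[seq_len(n_out)]
    }
  }
  epoch_set(out, epochs$labels, target_fs, epochs$channel_names,
            epochs$class_names, epochs$subject_id)
}

# small rational approximation of a resampling ratio
ratio_approx <- function(x, max_den = 1000L) {
  for (q in seq_len(max_den)) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) return(c(as.integer(round(p)), q))
  }
  abort(sprintf("cannot express resampling ratio %g as a small fraction", x))
}

#' Select (and reorder) channels by name
#'
#' Returns the epochs restricted to the named channels, in the order given
#' by `keep` — e.g. reducing a 128-channel high-density montage to a
#' 44-channel motor subset. Unknown names raise a validation error listing
#' what is missing.
#'
#' @param epochs an `epoch_set`.
#' @param keep character vector of channel names to retain, in output order.
#' @return an `epoch_set` with `length(keep)` channels.
#' @export
select_channels <- function(epochs, keep) {
  validate_epoch_set(epochs)
  idx <- match(keep, epochs$channel_names)
  if (anyNA(idx)) {
    abort(sprintf("unknown channel name(s): %s",
                  paste(keep[is.na(idx)], collapse = ", ")))
  }
  epoch_set(epochs$data[, idx, , drop = FALSE], epochs$labels, epochs$fs,
            epochs$channel_names[idx], epochs$class_names, epochs$subject_id)
}
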