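#' Epoched multichannel EEG container
#'
#' An `epoch_set` holds labelled, fixed-length multichannel EEG trials as a
#' 3-D numeric array of shape `n_trials x n_channels x n_samples`, together
#' with the sampling rate, channel names, class names and an optional subject
#' identifier. It is the common currency of the package: the synthetic
#' generator produces it, the preprocessing functions transform it, and the
#' networks train and evaluate on it.
#'
#' Labels are stored 0-based (`0 .. n_classes - 1`); event codes from
#' external datasets are mapped at ingestion so downstream indexing is
#' uniform.
#'
#' @param data numeric 3-D array, `n_trials x n_channels x n_samples`
#'   (amplitude in microvolts or standardized units).
#' @param labels integer vector of length `n_trials` with values in
#'   `0 .. length(class_names) - 1`.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_names character vector, one name per channel. Defaults to
#'   `"ch1", "ch2", ...`.
#' @param class_names character vector naming the classes. Defaults to
#'   `"class1", ...` up to `max(labels) + 1`.
#' @param subject_id optional subject identifier string.
#'
#' @return An object of class `epoch_set`.
#' @examples
#' x <- epoch_set(array(rnorm(10 * 3 * 50), c(10, 3, 50)),
#'                labels = rep(0:1, 5), fs = 250,
#'                class_names = c("left", "right"))
#' x
#' n_trials(x)
#' @export
epoch_set <- function(data, labels, fs, channel_names = NULL,
                      class_names = NULL, subject_id = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array (trials x channels x samples)")
  }
  storage.mode(data) <- "double"
  labels <- as.integer(labels)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(dim(data)[2]))
  if (is.null(class_names)) {
    n_cls <- if (length(labels)) max(labels) + 1L else 1L
    class_names <- paste0("class", seq_len(n_cls))
  }
  x <- structure(
    list(data = data, labels = labels, fs = as.numeric(fs),
         channel_names = as.character(channel_names),
         class_names = as.character(class_names),
         subject_id = if (is.null(subject_id)) NULL else as.character(subject_id)),
    class = "epoch_set")
  validate_epoch_set(x)
  x
}

#' Validate an epoch_set against its invariants
#'
#' Checks the structural invariants of the container: matching trial and
#' channel dimensions, labels within the class range, a positive sampling
#' rate and finite data. The error message names the failing field.
#'
#' @param x an `epoch_set`.
#' @return `x`, invisibly, if all invariants hold.
#' @export
validate_epoch_set <- function(x) {
  d <- dim(x$data)
  if (d[1] != length(x$labels)) {
    abort(sprintf(
      "invalid `labels`: length %d does not match %d trials in `data`",
      length(x$labels), d[1]))
  }
  if (d[2] != length(x$channel_names)) {
    abort(sprintf(
      "invalid `channel_names`: length %d does not match %d channels in `data`",
      length(x$channel_names), d[2]))
  }
  if (length(x$labels) && (min(x$labels) < 0L ||
                           max(x$labels) >= length(x$class_names))) {
    abort(sprintf(
      "invalid `labels`: values must lie in [0, %d)", length(x$class_names)))
  }
  if (!is.finite(x$fs) || x$fs <= 0) abort("invalid `fs`: must be > 0")
  if (length(x$data) && !all(is.finite(x$data))) {
    abort("invalid `data`: contains non-finite values")
  }
  invisible(x)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat("  classes:", paste(x$class_names, collapse = ", "), "\n")
  if (length(x$labels)) {
    tab <- table(factor(x$labels, levels = seq_along(x$class_names) - 1L))
    cat("  trials/class:", paste(as.integer(tab), collapse = "/"), "\n")
  }
  if (!is.null(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  invisible(x)
}

#' Number of trials in an epoch_set
#' @param x an `epoch_set`.
#' @return integer scalar.
#' @export
n_trials <- function(x) dim(x$data)[1]

#' Number of channels in an epoch_set
#' @param x an `epoch_set`.
#' @return integer scalar.
#' @export
n_channels <- function(x) dim(x$data)[2]

#' Number of samples per trial in an epoch_set
#' @param x an `epoch_set`.
#' @return integer scalar.
#' @export
n_samples <- function(x) dim(x$data)[3]

#' Subset the trials of an epoch_set
#'
#' @param x an `epoch_set`.
#' @param i trial indices (any standard R subscript).
#' @return an `epoch_set` with the selected trials.
#' @export
subset_epochs <- function(x, i) {
  epoch_set(x$data[i, , , drop = FALSE], x$labels[i], x$fs,
            x$channel_names, x$class_names, x$subject_id)
}

#' Summarise an epoch_set as a tibble
#'
#' One row per trial with its label and class name; handy for piping into
#' dplyr verbs when inspecting label balance.
#'
#' @param x an `epoch_set`.
#' @param ... unused.
#' @return a tibble with columns `trial`, `label`, `class`.
#' @export
as_tibble.epoch_set <- function(x, ...) {
  tibble(trial = seq_len(n_trials(x)),
         label = x$labels,
         class = x$class_names[x$labels + 1L])
}
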