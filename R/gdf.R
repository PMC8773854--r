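#' Standardize a continuous motor-imagery recording for epoching
#'
#' Adapter from a raw continuous recording (as delivered by any biosignal
#' reader) to the package's ingestion contract: EEG channels only, plus an
#' ordered table of `(cue_time, class)` events with 0-based class labels.
#' Ocular (EOG) channels are dropped via `channel_types`. Events whose code
#' is not in `event_codes` produce a warning and are skipped. An optional
#' keep/drop mask (e.g. the dataset's own artifact annotations) can remove
#' marked trials; the package takes no stance on what counts as an artifact.
#'
#' @param signal numeric matrix `n_channels x n_samples`.
#' @param fs sampling rate in Hz.
#' @param events data frame with columns `time` (seconds) and `code`.
#' @param event_codes named vector mapping class name -> event code; the
#'   order of its names defines the 0-based label assignment.
#' @param channel_names optional channel names (default from rownames).
#' @param channel_types optional character vector (`"eeg"` / `"eog"` / ...);
#'   only `"eeg"` channels are kept when supplied.
#' @param keep_mask optional logical vector over events after code matching;
#'   `FALSE` drops the trial (artifact-marked trials, typically).
#' @return a list with `signal` (EEG channels x samples), `fs`,
#'   `channel_names`, and `events`, a tibble with columns `time`, `class`
#'   (0-based integer) and `class_name`, in chronological order.
#' @export
standardize_mi_recording <- function(signal, fs, events, event_codes,
                                     channel_names = NULL,
                                     channel_types = NULL,
                                     keep_mask = NULL) {
  if (!is.matrix(signal)) abort("`signal` must be a channels x samples matrix")
  channel_names <- channel_names %||% rownames(signal) %||%
    paste0("ch", seq_len(nrow(signal)))
  if (!is.null(channel_types)) {
    keep <- tolower(channel_types) == "eeg"
    signal <- signal[keep, , drop = FALSE]
    channel_names <- channel_names[keep]
  }
  cls_idx <- match(events$code, unname(event_codes))
  if (anyNA(cls_idx)) {
    warn(sprintf("skipping %d event(s) with unknown code(s): %s",
                 sum(is.na(cls_idx)),
                 paste(unique(events$code[is.na(cls_idx)]), collapse = ", ")))
  }
  ev <- tibble(time = as.numeric(events$time),
               class = cls_idx - 1L,
               class_name = names(event_codes)[cls_idx])
  ev <- ev[!is.na(ev$class), , drop = FALSE]
  if (!is.null(keep_mask)) {
    if (length(keep_mask) != nrow(ev)) {
      abort("`keep_mask` length must match the number of recognised events")
    }
    ev <- ev[keep_mask, , drop = FALSE]
  }
  ev <- ev[order(ev$time), , drop = FALSE]
  list(signal = signal, fs = fs, channel_names = channel_names,
       events = ev, class_names = names(event_codes))
}

#' Read a GDF session through Python/MNE (optional bridge)
#'
#' GDF (the BCI Competition IV-2a session format) has no native R reader in
#' this package's dependency set, so this helper delegates parsing to the
#' MNE library through the `python` executable on the PATH, when available.
#' It returns the raw pieces that [standardize_mi_recording()] consumes.
#' Purely optional: every other function in the package works from
#' in-memory recordings or epoch archives.
#'
#' @param path path to a `.gdf` file.
#' @param python name/path of the python executable (default `"python"`).
#' @return a list with `signal`, `fs`, `channel_names`, `channel_types`,
#'   and `events` (data frame with `time`, `code`).
#' @export
read_gdf_raw <- function(path, python = "python") {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  if (Sys.which(python) == "") {
    abort("no python executable found; GDF ingestion needs Python with MNE")
  }
  tmp <- tempfile(fileext = ".h5")
  script <- c(
    "import sys, json, mne, h5py, numpy as np",
    "raw = mne.io.read_raw_gdf(sys.argv[1], preload=True, verbose='ERROR')",
    "ev, _ = mne.events_from_annotations(raw, verbose='ERROR')",
    "codes = {v: k for k, v in _.items()}",
    "with h5py.File(sys.argv[2], 'w') as f:",
    "    f['signal'] = raw.get_data().astype('float64')",
    "    f['ev_sample'] = ev[:, 0]",
    "    f['ev_code'] = np.array([codes[c] for c in ev[:, 2]], dtype=h5py.string_dtype())",
    "    f.attrs['fs'] = raw.info['sfreq']",
    "    f.attrs['ch_names'] = raw.ch_names",
    "    f.attrs['ch_types'] = raw.get_channel_types()")
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  on.exit(unlink(c(sf, tmp)), add = TRUE)
  status <- system2(python, c(sf, shQuote(path), shQuote(tmp)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(tmp)) {
    abort(sprintf("failed to parse '%s' via python/MNE", path))
  }
  raw <- cpp_h5_read_gdf_bridge(tmp)
  raw
}

#' Import one or more motor-imagery sessions from GDF files
#'
#' Convenience wrapper: parses each session with [read_gdf_raw()] and
#' normalises it with [standardize_mi_recording()] (dropping EOG channels
#' and mapping annotation codes to 0-based classes).
#'
#' @param session_paths character vector of `.gdf` paths.
#' @param event_codes named vector mapping class name -> annotation code
#'   (e.g. `c(left_hand = "769", right_hand = "770", feet = "771",
#'   tongue = "772")`).
#' @param ... passed on to [standardize_mi_recording()].
#' @return a list of standardized recordings, one per session.
#' @export
import_gdf_sessions <- function(session_paths, event_codes, ...) {
  purrr::map(session_paths, function(p) {
    raw <- read_gdf_raw(p)
    standardize_mi_recording(raw$signal, raw$fs, raw$events, event_codes,
                             channel_names = raw$channel_names,
                             channel_types = raw$channel_types, ...)
  })
}
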