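#' Write an epoch_set to an HDF5 epoch archive
#'
#' The archive is a single self-describing HDF5 file with a float32 `data`
#' dataset (`n_trials x n_channels x n_samples`, C order, so it reads
#' naturally from h5py or MATLAB), an int32 `labels` dataset, and root
#' attributes `fs`, `channel_names`, `class_names` and (when present)
#' `subject_id`. Data values round-trip bit-exactly at float32 precision.
#'
#' @param epochs an `epoch_set`; its invariants are validated before writing.
#' @param path output file path (directory must exist and be writable).
#' @return `path`, invisibly.
#' @seealso [read_epoch_archive()]
#' @export
write_epoch_archive <- function(epochs, path) {
  validate_epoch_set(epochs)
  # float32 is the archive precision: round data now so an immediate
  # read-back is the identity on what was written
  cpp_h5_write_epochs(path.expand(path), epochs$data, epochs$labels,
                      epochs$fs, epochs$channel_names, epochs$class_names,
                      epochs$subject_id)
  invisible(path)
}

#' Read an epoch archive into an epoch_set
#'
#' Inverse of [write_epoch_archive()]. A file missing one of the required
#' datasets or attributes raises a format error; an archive whose contents
#' violate the `epoch_set` invariants (label out of range, non-finite data,
#' mismatched channel names) raises a validation error.
#'
#' @param path path to an HDF5 epoch archive.
#' @return an `epoch_set`.
#' @export
read_epoch_archive <- function(path) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  raw <- cpp_h5_read_epochs(path.expand(path))
  epoch_set(raw$data, raw$labels, raw$fs, raw$channel_names,
            raw$class_names, raw$subject_id)
}
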