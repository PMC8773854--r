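test_that("epoch_set enforces its invariants with field-naming errors", {
  ok <- tiny_epochs()
  expect_s3_class(ok, "epoch_set")

  expect_error(
    epoch_set(array(0, c(10, 3, 40)), labels = rep(0L, 9), fs = 100),
    "labels")
  expect_error(
    epoch_set(array(0, c(2, 3, 4)), labels = c(0L, 5L), fs = 100,
              class_names = c("a", "b")),
    "labels")
  expect_error(
    epoch_set(array(0, c(2, 3, 4)), labels = c(0L, 1L), fs = -1), "fs")
  expect_error(
    epoch_set(array(c(NaN, rep(0, 23)), c(2, 3, 4)), labels = c(0L, 1L),
              fs = 100), "non-finite")
  expect_error(
    epoch_set(array(0, c(2, 3, 4)), labels = c(0L, 1L), fs = 100,
              channel_names = c("a", "b")), "channel_names")
})

test_that("archive write/read round-trips data and metadata bit-exactly", {
  x <- tiny_epochs(n = 10, n_ch = 22, n_s = 50, n_cls = 4, fs = 250)
  path <- withr::local_tempfile(fileext = ".h5")
  write_epoch_archive(x, path)
  y <- read_epoch_archive(path)
  expect_equal(dim(y$data), c(10, 22, 50))
  expect_equal(y$data, x$data, tolerance = 1e-7)  # float32 storage precision
  # once at float32 resolution, a second round trip is the exact identity
  path2 <- withr::local_tempfile(fileext = ".h5")
  write_epoch_archive(y, path2)
  z <- read_epoch_archive(path2)
  expect_epochs_equal(z, y)
  expect_identical(y$labels, x$labels)
  expect_identical(y$fs, x$fs)
  expect_identical(y$channel_names, x$channel_names)
  expect_identical(y$class_names, x$class_names)
})

test_that("a full benchmark-sized session (288 x 22 x 1125 at 250 Hz) round-trips", {
  x <- withr::with_seed(42, epoch_set(
    array(rnorm(288 * 22 * 1125), c(288, 22, 1125)),
    labels = rep(0:3, each = 72), fs = 250,
    class_names = c("left_hand", "right_hand", "feet", "tongue"),
    subject_id = "A01T"))
  path <- withr::local_tempfile(fileext = ".h5")
  write_epoch_archive(x, path)
  y <- read_epoch_archive(path)
  expect_equal(dim(y$data), c(288, 22, 1125))
  expect_equal(y$fs, 250)
  expect_identical(y$subject_id, "A01T")
  expect_equal(y$data, x$data, tolerance = 1e-7)  # float32 storage
  expect_identical(y$labels, x$labels)
})

test_that("reader rejects malformed or invariant-violating archives", {
  python <- Sys.which("python")
  expect_true(nzchar(python), info = "python with h5py expected on PATH")
  dir <- withr::local_tempdir()
  script <- file.path(dir, "make_bad.py")
  writeLines(c(
    "import h5py, numpy as np, sys",
    "d = sys.argv[1]",
    "with h5py.File(d + '/missing_labels.h5', 'w') as f:",
    "    f['data'] = np.zeros((2, 3, 4), dtype='float32')",
    "    f.attrs['fs'] = 100.0",
    "with h5py.File(d + '/bad_label.h5', 'w') as f:",
    "    f['data'] = np.zeros((2, 3, 4), dtype='float32')",
    "    f['labels'] = np.array([0, 7], dtype='int32')",
    "    f.attrs['fs'] = 100.0",
    "    f.attrs['channel_names'] = ['a', 'b', 'c']",
    "    f.attrs['class_names'] = ['x', 'y']",
    "with h5py.File(d + '/nonfinite.h5', 'w') as f:",
    "    f['data'] = np.full((2, 3, 4), np.nan, dtype='float32')",
    "    f['labels'] = np.array([0, 1], dtype='int32')",
    "    f.attrs['fs'] = 100.0",
    "    f.attrs['channel_names'] = ['a', 'b', 'c']",
    "    f.attrs['class_names'] = ['x', 'y']"), script)
  res <- system2(python, c(script, dir), stdout = TRUE, stderr = TRUE)
  expect_error(read_epoch_archive(file.path(dir, "missing_labels.h5")),
               "labels")
  expect_error(read_epoch_archive(file.path(dir, "bad_label.h5")),
               "labels")
  expect_error(read_epoch_archive(file.path(dir, "nonfinite.h5")),
               "non-finite")
  expect_error(read_epoch_archive(file.path(dir, "nope.h5")), "exist")
})

test_that("archives interoperate with h5py (written here, read there)", {
  python <- Sys.which("python")
  expect_true(nzchar(python))
  x <- tiny_epochs(n = 4, n_ch = 2, n_s = 10, fs = 250)
  path <- withr::local_tempfile(fileext = ".h5")
  write_epoch_archive(x, path)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import h5py, sys",
    "f = h5py.File(sys.argv[1], 'r')",
    "print(f['data'].shape, f['data'].dtype, f.attrs['fs'],",
    "      list(f.attrs['class_names']), f['labels'][:].sum())"), script)
  out <- system2(python, c(script, path), stdout = TRUE)
  expect_match(paste(out, collapse = " "), "\\(4, 2, 10\\) float32 250")
  expect_match(paste(out, collapse = " "), "'c1', 'c2'")
})

test_that("recording adapter maps events, drops EOG and tolerates empties", {
  sig <- matrix(rnorm(25 * 100), 25, 100)
  types <- c(rep("eeg", 22), rep("eog", 3))
  ev <- data.frame(time = c(2.0, 0.5, 1.2),
                   code = c("770", "769", "771"))
  codes <- c(left_hand = "769", right_hand = "770", feet = "771")
  out <- standardize_mi_recording(sig, 250, ev, codes, channel_types = types)
  expect_equal(nrow(out$signal), 22)
  expect_equal(out$events$time, c(0.5, 1.2, 2.0))
  expect_equal(out$events$class, c(0L, 2L, 1L))
  expect_equal(out$events$class_name, c("left_hand", "feet", "right_hand"))

  # unknown code: warn and skip
  ev2 <- rbind(ev, data.frame(time = 3, code = "999"))
  expect_warning(out2 <- standardize_mi_recording(sig, 250, ev2, codes),
                 "unknown")
  expect_equal(nrow(out2$events), 3)

  # artifact mask drops marked trials
  out3 <- standardize_mi_recording(sig, 250, ev, codes,
                                   keep_mask = c(TRUE, FALSE, TRUE))
  expect_equal(nrow(out3$events), 2)

  # empty event list: empty output, no error
  out4 <- standardize_mi_recording(
    sig, 250, data.frame(time = numeric(), code = character()), codes)
  expect_equal(nrow(out4$events), 0)
  ep <- extract_epochs(out4$signal, 250, out4$events$time,
                       window_spec(0.1, 0.2))
  expect_equal(n_trials(ep), 0)
})
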