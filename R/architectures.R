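#' EEGNet-style branch configuration
#'
#' One branch of the multibranch EEGNet family: a temporal convolution with
#' `n_temporal_filters` filters of length `kernel_length` samples
#' (same-padded, bias-free), batch norm, a depthwise spatial convolution
#' across all electrodes (multiplier `depth_multiplier`), batch norm + ELU,
#' temporal average pooling, dropout, then a separable convolution
#' (depthwise length `separable_kernel_length`, pointwise to
#' `pointwise_filters` maps), batch norm + ELU, a second average pooling and
#' dropout. The three default branches differ only in kernel size, filter
#' count and dropout rate, which is what lets the combined model pick up
#' oscillatory structure at several temporal scales at once.
#'
#' @param n_temporal_filters number of temporal filters (F1).
#' @param kernel_length temporal kernel length in samples (KE).
#' @param dropout_rate dropout probability in `[0, 1)`.
#' @param depth_multiplier spatial filters learned per temporal map (D).
#' @param pointwise_filters output maps of the separable convolution (F2);
#'   defaults to `depth_multiplier * n_temporal_filters`.
#' @param separable_kernel_length depthwise kernel length of the separable
#'   convolution (default 16).
#' @param pool_lengths lengths of the two temporal average pools
#'   (default `c(8, 8)`).
#' @return an object of class `eegnet_branch`.
#' @export
eegnet_branch <- function(n_temporal_filters, kernel_length, dropout_rate = 0,
                          depth_multiplier = 2L,
                          pointwise_filters = depth_multiplier * n_temporal_filters,
                          separable_kernel_length = 16L,
                          pool_lengths = c(8L, 8L)) {
  ints <- c(n_temporal_filters = n_temporal_filters,
            kernel_length = kernel_length,
            depth_multiplier = depth_multiplier,
            pointwise_filters = pointwise_filters,
            separable_kernel_length = separable_kernel_length,
            pool1 = pool_lengths[1], pool2 = pool_lengths[2])
  bad <- names(ints)[ints < 1 | ints != round(ints)]
  if (length(bad)) {
    abort(sprintf("branch field(s) %s must be positive integers",
                  paste(bad, collapse = ", ")))
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must lie in [0, 1)")
  }
  structure(list(n_temporal_filters = as.integer(n_temporal_filters),
                 kernel_length = as.integer(kernel_length),
                 dropout_rate = dropout_rate,
                 depth_multiplier = as.integer(depth_multiplier),
                 pointwise_filters = as.integer(pointwise_filters),
                 separable_kernel_length = as.integer(separable_kernel_length),
                 pool_lengths = as.integer(pool_lengths)),
            class = "eegnet_branch")
}

#' ShallowConvNet-style branch configuration
#'
#' One branch of the multibranch ShallowConvNet family: a valid temporal
#' convolution with `n_filters` filters of length `kernel_length`, a full
#' spatial convolution across electrodes and temporal maps, batch norm, a
#' squaring nonlinearity, overlapping temporal average pooling
#' (`pool_length` window, `pool_stride` step), a log activation
#' (`log(max(x, 1e-6))` for numeric safety) and dropout — the classic
#' band-power-like feature chain learned end to end.
#'
#' @param n_filters number of temporal (and spatial) filters (default 40).
#' @param kernel_length temporal kernel length in samples.
#' @param pool_length average-pooling window (default 75 samples).
#' @param pool_stride pooling stride (default 15 samples).
#' @param dropout_rate dropout probability (default 0.5).
#' @return an object of class `shallow_branch`.
#' @export
shallow_branch <- function(n_filters = 40L, kernel_length,
                           pool_length = 75L, pool_stride = 15L,
                           dropout_rate = 0.5) {
  ints <- c(n_filters = n_filters, kernel_length = kernel_length,
            pool_length = pool_length, pool_stride = pool_stride)
  bad <- names(ints)[ints < 1 | ints != round(ints)]
  if (length(bad)) {
    abort(sprintf("branch field(s) %s must be positive integers",
                  paste(bad, collapse = ", ")))
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must lie in [0, 1)")
  }
  structure(list(n_filters = as.integer(n_filters),
                 kernel_length = as.integer(kernel_length),
                 pool_length = as.integer(pool_length),
                 pool_stride = as.integer(pool_stride),
                 dropout_rate = dropout_rate),
            class = "shallow_branch")
}

#' Multibranch model specification
#'
#' Bundles an ordered list of same-family branches with the input
#' dimensions and class count. Branch outputs are flattened, concatenated
#' in declaration order and fed to a single dense softmax layer (with
#' bias); there are no per-branch dense sublayers.
#'
#' @param branches list of [eegnet_branch()] or [shallow_branch()] configs
#'   (all of one family).
#' @param n_channels number of EEG channels (E).
#' @param n_samples samples per trial (T).
#' @param n_classes number of output classes.
#' @return an object of class `mbeeg_spec`.
#' @export
multibranch_spec <- function(branches, n_channels = 22L, n_samples = 1125L,
                             n_classes = 4L) {
  if (!length(branches)) abort("at least one branch is required")
  fam <- unique(vapply(branches, function(b) class(b)[1], character(1)))
  if (length(fam) != 1L || !fam %in% c("eegnet_branch", "shallow_branch")) {
    abort("all branches must belong to one family (eegnet_branch or shallow_branch)")
  }
  if (n_channels < 1) abort("`n_channels` must be >= 1")
  ke <- vapply(branches, `[[`, integer(1), "kernel_length")
  if (any(ke > n_samples)) {
    abort("branch kernel_length must not exceed `n_samples`")
  }
  structure(list(family = if (fam == "eegnet_branch") "eegnet" else "shallow",
                 branches = branches,
                 n_channels = as.integer(n_channels),
                 n_samples = as.integer(n_samples),
                 n_classes = as.integer(n_classes)),
            class = "mbeeg_spec")
}

#' Three-branch EEGNet specification (MBEEGNet)
#'
#' The default branches are the global hyperparameters used for all
#' subjects: kernel sizes 16/32/64 with 4/8/16 temporal filters and dropout
#' 0/0.1/0.2, depth multiplier 2 and pointwise filters `2*F1` everywhere.
#' At the default 22 x 1125 input this model has 8,908 trainable
#' parameters.
#'
#' @inheritParams multibranch_spec
#' @param branches list of [eegnet_branch()] configs.
#' @return an `mbeeg_spec`.
#' @examples
#' spec <- mbeegnet_spec()
#' count_trainable_parameters(spec)$total  # 8908
#' @export
mbeegnet_spec <- function(n_channels = 22L, n_samples = 1125L, n_classes = 4L,
                          branches = list(
                            eegnet_branch(4L, 16L, 0),
                            eegnet_branch(8L, 32L, 0.1),
                            eegnet_branch(16L, 64L, 0.2))) {
  multibranch_spec(branches, n_channels, n_samples, n_classes)
}

#' Single-branch EEGNet specification
#'
#' The single-branch baseline: identical block structure to one branch of
#' [mbeegnet_spec()], followed by the same dense softmax layer.
#'
#' @inheritParams multibranch_spec
#' @param branch an [eegnet_branch()]; the default is the classic compact
#'   configuration (8 temporal filters, kernel 64, dropout 0.5).
#' @return an `mbeeg_spec` with one branch.
#' @export
eegnet_spec <- function(n_channels = 22L, n_samples = 1125L, n_classes = 4L,
                        branch = eegnet_branch(8L, 64L, 0.5)) {
  multibranch_spec(list(branch), n_channels, n_samples, n_classes)
}

#' Three-branch ShallowConvNet specification (MBShallowConvNet)
#'
#' Default kernel sizes are 5/15/20 samples with 40 filters per branch.
#'
#' @inheritParams multibranch_spec
#' @param kernel_lengths temporal kernel length of each branch.
#' @return an `mbeeg_spec`.
#' @export
mb_shallow_spec <- function(n_channels = 22L, n_samples = 1125L, n_classes = 4L,
                            kernel_lengths = c(5L, 15L, 20L)) {
  multibranch_spec(purrr::map(kernel_lengths,
                              ~shallow_branch(kernel_length = .x)),
                   n_channels, n_samples, n_classes)
}

#' Single-branch ShallowConvNet specification
#'
#' @inheritParams multibranch_spec
#' @param branch a [shallow_branch()]; default kernel length 25.
#' @return an `mbeeg_spec` with one branch.
#' @export
shallow_spec <- function(n_channels = 22L, n_samples = 1125L, n_classes = 4L,
                         branch = shallow_branch(kernel_length = 25L)) {
  multibranch_spec(list(branch), n_channels, n_samples, n_classes)
}

# ---------------------------------------------------------------------------
# per-branch layer tables (layer, shape, params, flattened output length)

eegnet_branch_layers <- function(b, n_channels, n_samples, tag) {
  f1 <- b$n_temporal_filters
  m <- f1 * b$depth_multiplier
  f2 <- b$pointwise_filters
  t1 <- n_samples %/% b$pool_lengths[1]
  t2 <- t1 %/% b$pool_lengths[2]
  if (t1 < 1 || t2 < 1) abort("pooling collapses the time axis to zero length")
  tibble(
    layer = paste0(tag, "_", c("temporal_conv", "batchnorm1",
                               "depthwise_spatial", "batchnorm2",
                               "separable_depthwise", "separable_pointwise",
                               "batchnorm3")),
    shape = c(sprintf("%dx%d", b$kernel_length, f1),
              sprintf("2x%d", f1),
              sprintf("%dx%d", n_channels, m),
              sprintf("2x%d", m),
              sprintf("%dx%d", b$separable_kernel_length, m),
              sprintf("%dx%d", m, f2),
              sprintf("2x%d", f2)),
    count = c(b$kernel_length * f1,
              2L * f1,
              n_channels * m,
              2L * m,
              b$separable_kernel_length * m,
              m * f2,
              2L * f2),
    flat = c(rep(NA_integer_, 6L), t2 * f2))
}

shallow_branch_layers <- function(b, n_channels, n_samples, tag) {
  f <- b$n_filters
  tv <- n_samples - b$kernel_length + 1L
  if (tv < b$pool_length) abort("pooling collapses the time axis to zero length")
  t2 <- (tv - b$pool_length) %/% b$pool_stride + 1L
  tibble(
    layer = paste0(tag, "_", c("temporal_conv", "spatial_conv", "batchnorm")),
    shape = c(sprintf("%dx%d", b$kernel_length, f),
              sprintf("%dx%d", n_channels * f, f),
              sprintf("2x%d", f)),
    count = c(b$kernel_length * f,
              n_channels * f * f,
              2L * f),
    flat = c(NA_integer_, NA_integer_, t2 * f))
}

spec_layer_table <- function(spec) {
  tabs <- purrr::imap(spec$branches, function(b, i) {
    tag <- paste0("branch", i)
    if (spec$family == "eegnet") {
      eegnet_branch_layers(b, spec$n_channels, spec$n_samples, tag)
    } else {
      shallow_branch_layers(b, spec$n_channels, spec$n_samples, tag)
    }
  })
  tab <- bind_rows(tabs)
  ftot <- sum(tab$flat, na.rm = TRUE)
  dense <- tibble(layer = c("dense", "dense_bias"),
                  shape = c(sprintf("%dx%d", ftot, spec$n_classes),
                            sprintf("%d", spec$n_classes)),
                  count = c(ftot * spec$n_classes, spec$n_classes),
                  flat = NA_integer_)
  bind_rows(tab, dense)
}

#' Audit the trainable parameters of a model specification
#'
#' Builds the per-layer parameter breakdown analytically from the
#' specification: convolution weights (all convolutions are bias-free),
#' dense weights plus bias, and two trainable batch-norm parameters (scale
#' and shift) per feature map. Running batch-norm statistics are not
#' trainable and are excluded. The same enumeration is available from a
#' built model via its actual weight tensors, which the test suite uses as
#' an independent cross-check.
#'
#' @param x an `mbeeg_spec` or a built `mbeeg_model`.
#' @return an object of class `mbeeg_param_audit`: a list with `entries`
#'   (tibble: `layer`, `shape`, `count`) and `total`.
#' @examples
#' count_trainable_parameters(mbeegnet_spec())$total  # 8908
#' @export
count_trainable_parameters <- function(x) {
  spec <- if (inherits(x, "mbeeg_model")) x$spec else x
  if (!inherits(spec, "mbeeg_spec")) {
    abort("`x` must be an mbeeg_spec or mbeeg_model")
  }
  tab <- spec_layer_table(spec)
  entries <- tibble(layer = tab$layer, shape = tab$shape,
                    count = as.integer(tab$count))
  structure(list(entries = entries, total = sum(entries$count)),
            class = "mbeeg_param_audit")
}

#' @export
print.mbeeg_param_audit <- function(x, ...) {
  cat("<parameter audit>\n")
  print(x$entries, n = Inf)
  cat("total trainable parameters:", x$total, "\n")
  invisible(x)
}

#' Multiplication count of a convolutional filter bank
#'
#' The flattened-filter cost argument: a bank of `n_filters` filters with
#' kernel extent `k_h x k_w x k_d` applied at `n_positions` positions costs
#' `n_filters * k_h * k_w * k_d * n_positions` multiplications. Splitting a
#' 3-D filter into a temporal 1-D and a spatial 1-D filter reduces, for
#' example, 528,000 multiplications to 8,000 + 4,620 = 12,620.
#'
#' @param n_filters number of filters.
#' @param kernel_dims integer vector of up to three kernel extents
#'   (missing trailing dimensions count as 1).
#' @param n_positions number of output positions the kernel is applied at.
#' @return integer multiplication count.
#' @examples
#' conv_multiplication_count(10, c(8, 1, 1), 100)   # 8000
#' conv_multiplication_count(10, c(1, 22, 1), 21)   # 4620
#' conv_multiplication_count(10, c(8, 22, 3), 100)  # 528000
#' @export
conv_multiplication_count <- function(n_filters, kernel_dims, n_positions) {
  kernel_dims <- c(kernel_dims, rep(1, 3 - length(kernel_dims)))
  vals <- c(n_filters = n_filters, kernel_dims, n_positions = n_positions)
  if (any(!is.finite(vals) | vals < 1 | vals != round(vals))) {
    abort("all arguments must be positive integers")
  }
  as.integer(n_filters * prod(kernel_dims) * n_positions)
}

#' Human-readable model summary
#'
#' Deterministic per-layer table of the compiled network: layer name,
#' output shape and trainable parameter count, with the same total as
#' [count_trainable_parameters()].
#'
#' @param spec an `mbeeg_spec` (or `mbeeg_model`).
#' @return a tibble of class `mbeeg_model_summary` with columns `layer`,
#'   `output_shape`, `params`; its `"total"` attribute holds the parameter
#'   total.
#' @export
describe_model <- function(spec) {
  if (inherits(spec, "mbeeg_model")) spec <- spec$spec
  rows <- list()
  for (i in seq_along(spec$branches)) {
    b <- spec$branches[[i]]
    tag <- paste0("branch", i)
    if (spec$family == "eegnet") {
      f1 <- b$n_temporal_filters; m <- f1 * b$depth_multiplier
      f2 <- b$pointwise_filters
      t1 <- spec$n_samples %/% b$pool_lengths[1]
      t2 <- t1 %/% b$pool_lengths[2]
      rows[[length(rows) + 1L]] <- tibble(
        layer = paste0(tag, "_", c("temporal_conv", "batchnorm1",
                                   "depthwise_spatial", "batchnorm2", "elu1",
                                   "avgpool1", "dropout1",
                                   "separable_conv", "batchnorm3", "elu2",
                                   "avgpool2", "dropout2", "flatten")),
        output_shape = c(
          sprintf("(%d, %d, %d)", f1, spec$n_channels, spec$n_samples),
          sprintf("(%d, %d, %d)", f1, spec$n_channels, spec$n_samples),
          sprintf("(%d, 1, %d)", m, spec$n_samples),
          rep(sprintf("(%d, 1, %d)", m, spec$n_samples), 2),
          rep(sprintf("(%d, 1, %d)", m, t1), 2),
          rep(sprintf("(%d, 1, %d)", f2, t1), 3),
          rep(sprintf("(%d, 1, %d)", f2, t2), 2),
          sprintf("(%d)", f2 * t2)),
        params = c(b$kernel_length * f1, 2L * f1, spec$n_channels * m,
                   2L * m, 0L, 0L, 0L,
                   b$separable_kernel_length * m + m * f2, 2L * f2,
                   0L, 0L, 0L, 0L))
    } else {
      f <- b$n_filters
      tv <- spec$n_samples - b$kernel_length + 1L
      t2 <- (tv - b$pool_length) %/% b$pool_stride + 1L
      rows[[length(rows) + 1L]] <- tibble(
        layer = paste0(tag, "_", c("temporal_conv", "spatial_conv",
                                   "batchnorm", "square", "avgpool", "log",
                                   "dropout", "flatten")),
        output_shape = c(
          sprintf("(%d, %d, %d)", f, spec$n_channels, tv),
          rep(sprintf("(%d, 1, %d)", f, tv), 3),
          rep(sprintf("(%d, 1, %d)", f, t2), 3),
          sprintf("(%d)", f * t2)),
        params = c(b$kernel_length * f, spec$n_channels * f * f, 2L * f,
                   0L, 0L, 0L, 0L, 0L))
    }
  }
  tab <- spec_layer_table(spec)
  ftot <- sum(tab$flat, na.rm = TRUE)
  if (length(spec$branches) > 1L) {
    rows[[length(rows) + 1L]] <- tibble(
      layer = "concatenate", output_shape = sprintf("(%d)", ftot), params = 0L)
  }
  rows[[length(rows) + 1L]] <- tibble(
    layer = "dense_softmax",
    output_shape = sprintf("(%d)", spec$n_classes),
    params = as.integer(ftot * spec$n_classes + spec$n_classes))
  out <- bind_rows(rows)
  attr(out, "total") <- sum(out$params)
  class(out) <- c("mbeeg_model_summary", class(out))
  out
}

#' @export
print.mbeeg_model_summary <- function(x, ...) {
  NextMethod(n = Inf)
  cat("total trainable parameters:", attr(x, "total"), "\n")
  invisible(x)
}
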