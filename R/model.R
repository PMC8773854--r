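#' Compile a model specification into a trainable network
#'
#' Instantiates the computation graph described by an `mbeeg_spec` in the
#' package's float32 engine, with glorot-uniform weight initialisation from
#' `seed`. The returned object carries the spec, the engine handle and a
#' training flag; [train_model()], [evaluate_model()] and
#' [predict.mbeeg_model()] operate on it. For any input, the network output
#' is a probability vector over the classes summing to one (softmax).
#'
#' @param spec an `mbeeg_spec`.
#' @param seed integer seed for weight initialisation (and any dropout
#'   noise drawn later during training).
#' @return an object of class `mbeeg_model`.
#' @examples
#' m <- build_model(mbeegnet_spec(), seed = 1)
#' m
#' @export
build_model <- function(spec, seed = 1L) {
  if (!inherits(spec, "mbeeg_spec")) abort("`spec` must be an mbeeg_spec")
  ptr <- cpp_model_new(unclass_spec(spec), as.integer(seed))
  structure(list(spec = spec, ptr = ptr, seed = as.integer(seed),
                 trained = FALSE, history = NULL),
            class = "mbeeg_model")
}

# strip S3 classes so the C++ side sees plain lists
unclass_spec <- function(spec) {
  s <- unclass(spec)
  s$branches <- lapply(s$branches, unclass)
  s
}

#' @export
print.mbeeg_model <- function(x, ...) {
  cat(sprintf("<mbeeg_model> family=%s branches=%d input=%dx%d classes=%d\n",
              x$spec$family, length(x$spec$branches), x$spec$n_channels,
              x$spec$n_samples, x$spec$n_classes))
  cat("  trainable parameters:", count_trainable_parameters(x)$total, "\n")
  cat("  trained:", x$trained, "\n")
  invisible(x)
}

#' Enumerate the weight tensors of a built model
#'
#' Walks every trainable variable actually allocated by the engine and
#' returns its name, shape and element count — the brute-force counterpart
#' of the analytic [count_trainable_parameters()] audit.
#'
#' @param model an `mbeeg_model`.
#' @return a tibble with columns `tensor`, `shape`, `count`.
#' @export
model_parameter_tensors <- function(model) {
  stopifnot(inherits(model, "mbeeg_model"))
  as_tibble(cpp_param_entries(model$ptr))
}

#' Extract or set the network weights
#'
#' `model_weights()` returns all parameter tensors (plus batch-norm running
#' statistics) as a named list of numeric arrays; `set_model_weights()`
#' writes such a list back. Together they allow persisting a trained model
#' or transplanting weights between identically-shaped models.
#'
#' @param model an `mbeeg_model`.
#' @return a named list of numeric matrices/vectors.
#' @export
model_weights <- function(model) {
  stopifnot(inherits(model, "mbeeg_model"))
  cpp_get_weights(model$ptr)
}

#' @rdname model_weights
#' @param weights named list as returned by `model_weights()`.
#' @export
set_model_weights <- function(model, weights) {
  stopifnot(inherits(model, "mbeeg_model"))
  cpp_set_weights(model$ptr, weights)
  invisible(model)
}

# internal: wrap an epoch_set as an engine dataset, checking shapes
as_engine_data <- function(model, epochs) {
  validate_epoch_set(epochs)
  if (n_channels(epochs) != model$spec$n_channels ||
      n_samples(epochs) != model$spec$n_samples) {
    abort(sprintf(
      "epochs (%d channels x %d samples) do not match the model input (%d x %d)",
      n_channels(epochs), n_samples(epochs),
      model$spec$n_channels, model$spec$n_samples))
  }
  if (length(epochs$labels) &&
      max(epochs$labels) >= model$spec$n_classes) {
    abort("epoch labels exceed the model's class count")
  }
  cpp_data_new(epochs$data, epochs$labels)
}

#' Predict class probabilities for an epoch_set
#'
#' Runs the network in inference mode (batch norm uses running statistics,
#' dropout disabled), so predictions are deterministic and identical
#' whether trials are scored singly or batched.
#'
#' @param object an `mbeeg_model`.
#' @param epochs an `epoch_set` matching the model input dimensions.
#' @param ... unused.
#' @return a numeric matrix `n_trials x n_classes` of probabilities; rows
#'   sum to one.
#' @export
predict.mbeeg_model <- function(object, epochs, ...) {
  if (n_trials(epochs) == 0L) abort("`epochs` contains no trials")
  d <- as_engine_data(object, epochs)
  p <- cpp_predict(object$ptr, d)
  colnames(p) <- epochs$class_names[seq_len(object$spec$n_classes)]
  p
}
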