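#' Training configuration
#'
#' The within-subject training recipe: Adam with learning rate 0.0009,
#' batch size 64, categorical cross-entropy, and a per-epoch callback that
#' keeps the weights of the epoch with the best monitored accuracy. The
#' monitored split is explicit: `"eval"` watches the held-out evaluation
#' set (the protocol the accompanying results follow, but leakage-prone —
#' see the methods vignette), `"train"` re-evaluates the training set in
#' inference mode after each epoch (so the monitored value is exactly
#' reproducible from the restored checkpoint), and `"none"` disables the
#' callback and keeps the final-epoch weights.
#'
#' @param epochs number of passes over the training data (default 1000).
#' @param batch_size mini-batch size (default 64).
#' @param learning_rate optimizer step size (default 0.0009).
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param monitor_split `"eval"` (default), `"train"`, or `"none"`.
#' @param seed integer seed controlling shuffling and dropout.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 1000L, batch_size = 64L,
                         learning_rate = 9e-4,
                         optimizer = c("adam", "sgd"),
                         monitor_split = c("eval", "train", "none"),
                         seed = 1L) {
  optimizer <- match.arg(optimizer)
  monitor_split <- match.arg(monitor_split)
  if (epochs < 1 || batch_size < 1) {
    abort("`epochs` and `batch_size` must be >= 1")
  }
  if (learning_rate < 0) abort("`learning_rate` must be >= 0")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 monitor_split = monitor_split, seed = as.integer(seed)),
            class = "train_config")
}

#' Train a model with best-checkpoint restoration
#'
#' Runs mini-batch gradient training (seeded shuffling each epoch, no data
#' augmentation) and evaluates the monitored split after every epoch. At
#' the end, the weights of the epoch with the highest monitored accuracy
#' are restored (ties broken toward the earliest epoch), mirroring a
#' best-weights checkpoint callback. Fully reproducible: the same seed
#' yields the same history and the same final weights.
#'
#' @param model an `mbeeg_model` (freshly built; it is modified in place
#'   and also returned).
#' @param train_set `epoch_set` used for gradient updates.
#' @param monitor_set `epoch_set` watched by the checkpoint callback when
#'   `monitor_split = "eval"` (typically the held-out session).
#' @param config a [train_config()].
#' @return the trained model, whose `$history` is an `mbeeg_history`:
#'   a tibble with per-epoch `epoch`, `train_loss`, `train_accuracy`,
#'   `monitor_accuracy`, plus attributes `best_epoch` and `best_accuracy`.
#' @export
train_model <- function(model, train_set, monitor_set = NULL,
                        config = train_config()) {
  stopifnot(inherits(model, "mbeeg_model"))
  if (!inherits(config, "train_config")) abort("`config` must be a train_config")
  if (n_trials(train_set) == 0L) abort("`train_set` contains no trials")
  if (config$monitor_split == "eval" && is.null(monitor_set)) {
    abort("monitor_split = \"eval\" requires a `monitor_set`")
  }
  d_train <- as_engine_data(model, train_set)
  d_mon <- switch(config$monitor_split,
                  eval = as_engine_data(model, monitor_set),
                  train = d_train,
                  none = NULL)
  mon_labels <- switch(config$monitor_split,
                       eval = monitor_set$labels,
                       train = train_set$labels,
                       none = NULL)

  # reseed the engine RNG from the config seed so shuffling/dropout are
  # reproducible regardless of how many draws initialisation consumed
  cpp_reseed(model$ptr, config$seed)
  hist <- vector("list", config$epochs)
  best_acc <- -Inf
  best_epoch <- NA_integer_

  for (ep in seq_len(config$epochs)) {
    res <- cpp_train_epoch(model$ptr, d_train, config$batch_size,
                           config$learning_rate, config$optimizer)
    if (!is.finite(res$loss)) {
      abort(sprintf("non-finite training loss at epoch %d", ep))
    }
    mon_acc <- if (is.null(d_mon)) {
      NA_real_
    } else {
      p <- cpp_predict(model$ptr, d_mon)
      mean(max.col(p, ties.method = "first") - 1L == mon_labels)
    }
    hist[[ep]] <- c(train_loss = res$loss, train_accuracy = res$accuracy,
                    monitor_accuracy = mon_acc)
    if (!is.na(mon_acc) && mon_acc > best_acc) {  # ties keep the earliest epoch
      best_acc <- mon_acc
      best_epoch <- ep
      cpp_snapshot(model$ptr)
    }
  }
  if (config$monitor_split == "none") {
    best_acc <- NA_real_
    best_epoch <- config$epochs
  } else {
    cpp_restore(model$ptr)
  }
  cpp_free_caches(model$ptr)
  h <- as_tibble(do.call(rbind, hist))
  h <- tibble(epoch = seq_len(config$epochs), h)
  attr(h, "best_epoch") <- best_epoch
  attr(h, "best_accuracy") <- best_acc
  attr(h, "monitor_split") <- config$monitor_split
  class(h) <- c("mbeeg_history", class(h))
  model$trained <- TRUE
  model$history <- h
  model
}

#' @export
print.mbeeg_history <- function(x, ...) {
  if (attr(x, "monitor_split") == "none") {
    cat(sprintf("<training history> %d epochs (no checkpoint monitoring)\n",
                nrow(x)))
  } else {
    cat(sprintf("<training history> %d epochs; best %s accuracy %.4f at epoch %d\n",
                nrow(x), attr(x, "monitor_split"), attr(x, "best_accuracy"),
                attr(x, "best_epoch")))
  }
  NextMethod()
}

#' Evaluate a model on a test set
#'
#' Predicts every trial (argmax of the softmax output, ties toward the
#' lowest class index) and derives the full metric report from the
#' confusion matrix.
#'
#' @param model a built (typically trained) `mbeeg_model`.
#' @param test_set a non-empty `epoch_set`.
#' @param pe_mode chance-agreement mode for kappa, see [metrics_from_cm()].
#' @return an `mbeeg_eval`: list with `predictions` (tibble: `trial`,
#'   `truth`, `predicted`, per-class probabilities) and `report`
#'   (an `mbeeg_eval_report`).
#' @export
evaluate_model <- function(model, test_set, pe_mode = "marginals") {
  if (n_trials(test_set) == 0L) abort("`test_set` contains no trials")
  p <- predict(model, test_set)
  pred <- max.col(p, ties.method = "first") - 1L
  cm <- confusion_matrix(test_set$labels, pred, model$spec$n_classes,
                         class_names = test_set$class_names)
  report <- metrics_from_cm(cm, pe_mode = pe_mode)
  predictions <- tibble(trial = seq_len(n_trials(test_set)),
                        truth = test_set$labels,
                        predicted = pred)
  predictions <- dplyr::bind_cols(predictions, as_tibble(p))
  structure(list(predictions = predictions, report = report),
            class = "mbeeg_eval")
}

#' @export
print.mbeeg_eval <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Categorical cross-entropy
#'
#' The loss minimised during training: `-sum(t * log(p))` for a one-hot
#' truth vector `t` and predicted probabilities `p`. The log base is
#' configurable; training itself uses the natural log (a base change only
#' rescales gradients, which the learning rate absorbs), while base 2
#' expresses the loss in bits.
#'
#' @param p numeric probability vector (or matrix, rows = observations).
#' @param truth 0-based true class index (or vector of them).
#' @param base logarithm base (default `exp(1)`).
#' @return the mean cross-entropy over the observations.
#' @examples
#' cross_entropy(c(0.25, 0.25, 0.25, 0.25), 0, base = 2)  # 2 bits
#' @export
cross_entropy <- function(p, truth, base = exp(1)) {
  if (is.vector(p)) p <- matrix(p, nrow = 1)
  idx <- cbind(seq_len(nrow(p)), as.integer(truth) + 1L)
  mean(-log(pmax(p[idx], 1e-300)) / log(base))
}
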