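#' Tidy an evaluation report
#'
#' @param x an `mbeeg_eval_report`.
#' @param ... unused.
#' @return the per-class metric tibble (`class`, counts, `precision`,
#'   `recall`, `f1`).
#' @export
tidy.mbeeg_eval_report <- function(x, ...) x$per_class

#' One-row summary of an evaluation report
#'
#' @param x an `mbeeg_eval_report`.
#' @param ... unused.
#' @return a one-row tibble: `accuracy`, `kappa`, macro `precision`,
#'   `recall`, `f1`, and `n` scored trials.
#' @export
glance.mbeeg_eval_report <- function(x, ...) {
  dplyr::bind_cols(x$macro, tibble(n = sum(x$confusion)))
}

#' @export
tidy.mbeeg_eval <- function(x, ...) tidy(x$report)

#' @export
glance.mbeeg_eval <- function(x, ...) glance(x$report)

#' Tidy a parameter audit
#' @param x an `mbeeg_param_audit`.
#' @param ... unused.
#' @return the per-layer entries tibble.
#' @export
tidy.mbeeg_param_audit <- function(x, ...) x$entries

#' @export
glance.mbeeg_param_audit <- function(x, ...) {
  tibble(n_layers = nrow(x$entries), total = x$total)
}

#' One-row summary of a (possibly trained) model
#' @param x an `mbeeg_model`.
#' @param ... unused.
#' @export
glance.mbeeg_model <- function(x, ...) {
  tibble(family = x$spec$family,
         n_branches = length(x$spec$branches),
         n_channels = x$spec$n_channels,
         n_samples = x$spec$n_samples,
         n_classes = x$spec$n_classes,
         n_parameters = count_trainable_parameters(x)$total,
         trained = x$trained,
         best_accuracy = if (is.null(x$history)) NA_real_
                         else attr(x$history, "best_accuracy"))
}

#' Plot training curves
#'
#' Loss and accuracy per epoch (training loss, training accuracy and the
#' monitored accuracy), with the best epoch marked.
#'
#' @param object an `mbeeg_history`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mbeeg_history <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    cols = c("train_loss", "train_accuracy", "monitor_accuracy"),
    names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "best_epoch"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~ifelse(grepl("loss", series), "loss", "accuracy"),
                        scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL)
}

#' Plot a confusion matrix as a heat map
#'
#' @param object an `mbeeg_eval_report` (or `mbeeg_cm`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mbeeg_eval_report <- function(object, ...) {
  cm <- object$confusion
  df <- as.data.frame(as.table(unclass(cm)))
  names(df) <- c("truth", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev(rownames(cm))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted class", y = "true class")
}
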