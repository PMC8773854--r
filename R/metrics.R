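#' Confusion matrix from true and predicted labels
#'
#' Cell `(i, j)` counts trials with true class `i` predicted as class `j`
#' (0-based labels; rows = truth, columns = prediction). The total count
#' `C` equals the number of scored trials.
#'
#' @param y_true,y_pred integer vectors of equal length with values in
#'   `0 .. n_classes - 1`.
#' @param n_classes number of classes.
#' @param class_names optional class names used as dimnames.
#' @return an integer `n_classes x n_classes` matrix of class `mbeeg_cm`.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes,
                             class_names = NULL) {
  if (length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must have equal length")
  }
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) &&
      (min(y_true, y_pred) < 0L || max(y_true, y_pred) >= n_classes)) {
    abort(sprintf("labels must lie in [0, %d)", n_classes))
  }
  lev <- 0:(n_classes - 1L)
  cm <- table(factor(y_true, levels = lev), factor(y_pred, levels = lev))
  cm <- matrix(as.integer(cm), n_classes, n_classes)
  nm <- class_names %||% paste0("class", seq_len(n_classes))
  dimnames(cm) <- list(truth = nm, predicted = nm)
  class(cm) <- c("mbeeg_cm", class(cm))
  cm
}

#' One-vs-rest counts for a class
#'
#' Reduces the multiclass confusion matrix to binary counts for class `k`:
#' `TP = cm[k, k]`, `FP` = rest of column `k`, `FN` = rest of row `k`,
#' `TN = C - TP - FP - FN`; the four always sum to the total trial count.
#'
#' @param cm a confusion matrix (rows = truth).
#' @param k 0-based class index.
#' @return named integer vector `c(tp, tn, fp, fn)`.
#' @export
one_vs_rest_counts <- function(cm, k) {
  i <- as.integer(k) + 1L
  if (i < 1L || i > nrow(cm)) abort("`k` out of range")
  total <- sum(cm)
  tp <- cm[i, i]
  fp <- sum(cm[, i]) - tp
  fn <- sum(cm[i, ]) - tp
  c(tp = tp, tn = total - tp - fp - fn, fp = fp, fn = fn)
}

#' Full metric report from a confusion matrix
#'
#' Computes overall accuracy (`trace / C`), Cohen's kappa
#' `(Po - Pe) / (1 - Pe)` with `Po` the observed agreement (accuracy) and
#' `Pe` the chance agreement, per-class precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and F1 `2PR/(P+R)`, and their unweighted macro averages.
#'
#' `pe_mode` controls the chance-agreement term: `"marginals"` (default)
#' uses the product of row and column marginals,
#' `Pe = sum_k (TP_k+FP_k)(TP_k+FN_k) / C^2`; `"uniform"` fixes
#' `Pe = 1 / n_classes`, the value the marginal formula takes for a
#' balanced test set with balanced predictions. Degenerate cases: an empty
#' precision/recall denominator yields 0 with a warning, and `Pe = 1`
#' (total marginal agreement, kappa undefined 0/0) yields kappa 0 with a
#' warning.
#'
#' @param cm a square confusion matrix (rows = truth).
#' @param pe_mode `"marginals"` or `"uniform"`.
#' @return an `mbeeg_eval_report`: list with `confusion`, `accuracy`,
#'   `kappa`, `po`, `pe`, `per_class` (tibble: `class`, `tp`, `tn`, `fp`,
#'   `fn`, `precision`, `recall`, `f1`) and `macro` (one-row tibble).
#' @examples
#' cm <- confusion_matrix(rep(0:3, each = 10),
#'                        c(rep(0, 9), 1, rep(1, 9), 2,
#'                          rep(2, 9), 3, rep(3, 9), 0), 4)
#' metrics_from_cm(cm)$kappa  # (0.9 - 0.25) / 0.75
#' @export
metrics_from_cm <- function(cm, pe_mode = c("marginals", "uniform")) {
  pe_mode <- match.arg(pe_mode)
  total <- sum(cm)
  if (total == 0) abort("confusion matrix is empty (C = 0)")
  k <- nrow(cm)
  po <- sum(diag(cm)) / total
  pe <- if (pe_mode == "marginals") {
    sum(rowSums(cm) * colSums(cm)) / total^2
  } else {
    1 / k
  }
  kappa <- if (abs(1 - pe) < .Machine$double.eps * 8) {
    warn("chance agreement Pe = 1; kappa is undefined and reported as 0")
    0
  } else {
    (po - pe) / (1 - pe)
  }
  per_class <- purrr::map_dfr(seq_len(k) - 1L, function(cls) {
    cnt <- one_vs_rest_counts(cm, cls)
    prec <- safe_ratio(cnt["tp"], cnt["tp"] + cnt["fp"], "precision",
                       rownames(cm)[cls + 1L])
    rec <- safe_ratio(cnt["tp"], cnt["tp"] + cnt["fn"], "recall",
                      rownames(cm)[cls + 1L])
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    tibble(class = rownames(cm)[cls + 1L],
           tp = unname(cnt["tp"]), tn = unname(cnt["tn"]),
           fp = unname(cnt["fp"]), fn = unname(cnt["fn"]),
           precision = prec, recall = rec, f1 = f1)
  })
  macro <- tibble(accuracy = po, kappa = kappa,
                  precision = mean(per_class$precision),
                  recall = mean(per_class$recall),
                  f1 = mean(per_class$f1))
  structure(list(confusion = cm, accuracy = po, kappa = kappa,
                 po = po, pe = pe, per_class = per_class, macro = macro,
                 pe_mode = pe_mode),
            class = "mbeeg_eval_report")
}

safe_ratio <- function(num, den, what, cls) {
  if (den == 0) {
    warn(sprintf("%s undefined for class %s (empty denominator); using 0",
                 what, cls))
    return(0)
  }
  unname(num / den)
}

#' @export
print.mbeeg_eval_report <- function(x, ...) {
  cat(sprintf("<eval report> accuracy %.4f, kappa %.4f (Pe %s)\n",
              x$accuracy, x$kappa, x$pe_mode))
  print(x$per_class)
  invisible(x)
}

#' Aggregate per-subject metric values
#'
#' Summarises per-subject results the way benchmark tables report them:
#' arithmetic mean and sample standard deviation (n - 1 denominator, which
#' is what reproduces published summary rows from published per-subject
#' values). Accepts a bare numeric vector or a data frame, in which case
#' every numeric column is summarised.
#'
#' @param x numeric vector of per-subject values, or a data frame.
#' @param ... unused.
#' @return a tibble with columns `metric`, `n`, `mean`, `sd` (`sd` is `NA`
#'   for a single value).
#' @examples
#' aggregate_subjects(c(89.59, 68.06, 94.58, 79.88, 76.92,
#'                      66.10, 91.57, 87.71, 83.69))
#' @export
aggregate_subjects <- function(x, ...) UseMethod("aggregate_subjects")

#' @export
aggregate_subjects.numeric <- function(x, ...) {
  if (length(x) < 1L) abort("at least one value is required")
  tibble(metric = "value", n = length(x), mean = mean(x),
         sd = if (length(x) >= 2L) sd(x) else NA_real_)
}

#' @export
aggregate_subjects.data.frame <- function(x, ...) {
  num <- names(x)[vapply(x, is.numeric, logical(1))]
  if (!length(num)) abort("no numeric columns to aggregate")
  purrr::map_dfr(num, function(col) {
    v <- x[[col]]
    v <- v[!is.na(v)]
    if (length(v) < 1L) abort(sprintf("column '%s' has no values", col))
    tibble(metric = col, n = length(v), mean = mean(v),
           sd = if (length(v) >= 2L) sd(v) else NA_real_)
  })
}

#' Export a metric table as CSV
#'
#' Writes a per-subject metric table (one row per subject) to CSV for use
#' outside R, matching the layout of published per-subject result tables.
#'
#' @param x a data frame (e.g. bound [glance()] rows per subject).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_metrics_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
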