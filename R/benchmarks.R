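#' Published per-subject benchmark results
#'
#' Per-subject classification accuracies (and, for the 9-subject
#' four-class cue-based benchmark, kappa scores) reported for the
#' architectures implemented here on the two standard motor-imagery
#' benchmarks: BCI Competition IV-2a (9 subjects, within-subject
#' session-to-session transfer) and the High Gamma Dataset (14 subjects).
#' Shipped as plain CSV so the aggregation utilities can be exercised and
#' regression-tested against the corresponding published summary rows
#' without downloading or training anything.
#'
#' @param dataset `"bciiv2a"` or `"hgd"`.
#' @return a tibble with columns `model`, `subject`, `accuracy` (and
#'   `kappa` for `"bciiv2a"`), accuracies in percent.
#' @examples
#' reference_results("bciiv2a") %>%
#'   dplyr::filter(model == "mbeegnet") %>%
#'   dplyr::pull(accuracy) %>%
#'   aggregate_subjects()
#' @export
reference_results <- function(dataset = c("bciiv2a", "hgd")) {
  dataset <- match.arg(dataset)
  path <- system.file("extdata", paste0(dataset, "_reference_results.csv"),
                      package = "mbeeg", mustWork = TRUE)
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Published summary rows for the 9-subject benchmark
#'
#' The mean / standard-deviation summary rows as published (accuracy and
#' kappa, in percent / absolute). Note that for the single-branch
#' ShallowConvNet baseline the published mean (74.31) differs slightly
#' from the mean of its own published per-subject values (74.25); the
#' published row is kept verbatim here and deltas against baselines are
#' conventionally quoted from these rows.
#'
#' @return a tibble with columns `model`, `mean_accuracy`, `sd_accuracy`,
#'   `mean_kappa`, `sd_kappa`.
#' @export
reference_summary <- function() {
  path <- system.file("extdata", "bciiv2a_reference_summary.csv",
                      package = "mbeeg", mustWork = TRUE)
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
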