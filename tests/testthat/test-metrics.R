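test_that("confusion matrices count truth rows against prediction columns", {
  cm <- confusion_matrix(0:3, 0:3, 4)
  expect_true(all(cm == diag(1, 4)))
  expect_equal(sum(cm), 4L)

  cm2 <- confusion_matrix(c(0, 0), c(1, 1), 2)
  expect_equal(cm2[1, 2], 2L)
  expect_equal(sum(cm2), 2L)

  y <- withr::with_seed(1, sample(0:3, 1000, replace = TRUE))
  p <- withr::with_seed(2, sample(0:3, 1000, replace = TRUE))
  expect_equal(sum(confusion_matrix(y, p, 4)), 1000L)

  expect_error(confusion_matrix(0:2, 0:1, 3), "length")
  expect_error(confusion_matrix(c(0, 4), c(0, 1), 4), "labels")
})

test_that("one-vs-rest counts conserve the total", {
  cm <- confusion_matrix(rep(0:3, each = 10), rep(0:3, each = 10), 4)
  expect_equal(one_vs_rest_counts(cm, 0),
               c(tp = 10L, tn = 30L, fp = 0L, fn = 0L))

  all_one_col <- matrix(0L, 4, 4)
  all_one_col[, 2] <- c(5L, 7L, 3L, 1L)
  expect_equal(one_vs_rest_counts(all_one_col, 1)[["fp"]], 16L - 7L)

  y <- withr::with_seed(3, sample(0:3, 200, replace = TRUE))
  p <- withr::with_seed(4, sample(0:3, 200, replace = TRUE))
  cmr <- confusion_matrix(y, p, 4)
  for (k in 0:3) expect_equal(sum(one_vs_rest_counts(cmr, k)), 200L)
})

test_that("metric report reproduces hand-derived values", {
  # perfect balanced matrix
  rep1 <- metrics_from_cm(confusion_matrix(rep(0:3, 10), rep(0:3, 10), 4))
  expect_equal(rep1$accuracy, 1)
  expect_equal(rep1$kappa, 1)
  expect_true(all(rep1$per_class$precision == 1))
  expect_true(all(rep1$per_class$f1 == 1))

  # constant predictor on balanced data: Po = Pe = 0.25, kappa = 0
  cmc <- matrix(0L, 4, 4); cmc[, 1] <- 10L
  dimnames(cmc) <- list(letters[1:4], letters[1:4])
  w <- capture_warnings(rep2 <- metrics_from_cm(cmc))
  expect_true(any(grepl("precision", w)))  # empty denominators warn per class
  expect_equal(rep2$po, 0.25)
  expect_equal(rep2$pe, 0.25)
  expect_equal(rep2$kappa, 0)

  # 90% diagonal with uniform errors: kappa = (0.9 - 0.25) / 0.75
  cm3 <- matrix(1L, 4, 4); diag(cm3) <- 27L   # rows: 27 + 3 errors of 1
  rep3 <- metrics_from_cm(cm3)
  expect_equal(rep3$accuracy, 0.9)
  expect_equal(rep3$kappa, (0.9 - 0.25) / 0.75)
  expect_equal(rep3$kappa, 0.8667, tolerance = 1e-4)

  # uniform-Pe mode fixes the chance term at 1/k
  cm4 <- confusion_matrix(c(0, 0, 1, 2), c(0, 1, 1, 2), 3)
  repu <- metrics_from_cm(cm4, pe_mode = "uniform")
  expect_equal(repu$pe, 1 / 3)

  expect_error(metrics_from_cm(matrix(0L, 3, 3)), "C = 0")
  # total marginal agreement: kappa undefined, reported as 0
  degen <- matrix(c(5L, 0L, 0L, 0L), 2, 2)
  w2 <- capture_warnings(repd <- metrics_from_cm(degen))
  expect_true(any(grepl("Pe = 1", w2)))
  expect_equal(repd$kappa, 0)
})

test_that("kappa always lies within bounds and below accuracy", {
  withr::with_seed(42, {
    for (i in 1:50) {
      k <- sample(2:6, 1)
      cm <- matrix(rpois(k * k, 3), k, k)
      if (sum(cm) == 0) cm[1, 1] <- 1
      suppressWarnings(r <- metrics_from_cm(cm))
      expect_gte(r$kappa, -1)
      expect_lte(r$kappa, 1)
      expect_lte(r$kappa, r$accuracy + 1e-12)  # holds whenever Pe >= 0
    }
  })
})

test_that("tidy/glance expose per-class and summary views", {
  cm <- confusion_matrix(rep(0:1, c(6, 4)), c(rep(0, 5), rep(1, 5)), 2,
                         class_names = c("left", "right"))
  r <- metrics_from_cm(cm)
  td <- tidy(r)
  expect_equal(td$class, c("left", "right"))
  expect_equal(td$tp, c(5, 4))        # trial 6 (true left) predicted right
  expect_equal(td$precision, c(1, 4 / 5))
  g <- glance(r)
  expect_equal(g$n, 10)
  expect_equal(g$accuracy, 0.9)
})

test_that("subject aggregation uses mean and sample (n-1) deviation", {
  agg <- aggregate_subjects(c(1, 2, 3, 4))
  expect_equal(agg$mean, 2.5)
  expect_equal(agg$sd, sd(c(1, 2, 3, 4)))  # n-1 convention

  expect_equal(aggregate_subjects(rep(7, 5))$sd, 0)
  expect_true(is.na(aggregate_subjects(5)$sd))
  expect_error(aggregate_subjects(numeric(0)), "at least one")

  df <- data.frame(subject = c("a", "b", "c"),
                   accuracy = c(80, 90, 100), kappa = c(0.7, 0.8, 0.9))
  agg2 <- aggregate_subjects(df)
  expect_equal(agg2$metric, c("accuracy", "kappa"))
  expect_equal(agg2$mean, c(90, 0.8))
  expect_equal(agg2$n, c(3L, 3L))
})

test_that("metric tables export as per-subject CSV", {
  df <- tibble::tibble(subject = c("S1", "S2"), accuracy = c(80.1, 75.2),
                       kappa = c(0.73, 0.67))
  path <- withr::local_tempfile(fileext = ".csv")
  export_metrics_csv(df, path)
  back <- utils::read.csv(path)
  expect_equal(back$accuracy, df$accuracy)
  expect_equal(nrow(back), 2)
})
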