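# small separable problem used across the training tests
separable_set <- function(n_per_class = 4, n_ch = 4, n_s = 160, fs = 100,
                          seed = 1) {
  withr::with_seed(seed, {
    n <- 4 * n_per_class
    data <- array(rnorm(n * n_ch * n_s, sd = 0.2), c(n, n_ch, n_s))
    t_s <- (seq_len(n_s) - 1) / fs
    labels <- rep(0:3, each = n_per_class)
    for (i in seq_len(n)) {
      ch <- labels[i] + 1L
      data[i, ch, ] <- data[i, ch, ] + sin(2 * pi * 10 * t_s + runif(1, 0, 6))
    }
    epoch_set(data, labels, fs, class_names = paste0("k", 1:4))
  })
}

small_spec <- function(dropout = 0) {
  multibranch_spec(list(eegnet_branch(4, 16, dropout)), 4, 160, 4)
}

test_that("a small network memorises a separable toy set (overfit sanity)", {
  x <- separable_set()
  m <- build_model(small_spec(), seed = 1)
  m <- train_model(m, x, config = train_config(epochs = 200, batch_size = 8,
                                               monitor_split = "train",
                                               seed = 1))
  h <- m$history
  expect_equal(tail(h$train_accuracy, 1), 1.0)
  expect_equal(attr(h, "best_accuracy"), 1.0)
  # evaluating on the training set of the overfit example
  ev <- evaluate_model(m, x)
  expect_equal(ev$report$accuracy, 1.0)
})

test_that("training is reproducible: same seed, same history and weights", {
  x <- separable_set()
  cfg <- train_config(epochs = 8, batch_size = 8, monitor_split = "train",
                      seed = 7)
  m1 <- train_model(build_model(small_spec(0.2), seed = 3), x, config = cfg)
  m2 <- train_model(build_model(small_spec(0.2), seed = 3), x, config = cfg)
  expect_identical(as.data.frame(m1$history), as.data.frame(m2$history))
  expect_identical(model_weights(m1), model_weights(m2))
  # a different seed shuffles/drops differently
  cfg2 <- train_config(epochs = 8, batch_size = 8, monitor_split = "train",
                       seed = 8)
  m3 <- train_model(build_model(small_spec(0.2), seed = 3), x, config = cfg2)
  expect_false(identical(as.data.frame(m1$history),
                         as.data.frame(m3$history)))
})

test_that("zero learning rate leaves weights unchanged with a flat loss", {
  x <- separable_set()
  m <- build_model(small_spec(0), seed = 2)
  w0 <- model_weights(m)
  # full-batch so batch-norm statistics cannot vary with the shuffle
  m <- train_model(m, x, config = train_config(epochs = 5, batch_size = 16,
                                               learning_rate = 0,
                                               monitor_split = "train",
                                               seed = 1))
  w1 <- model_weights(m)
  for (nm in setdiff(names(w0), grep("running", names(w0), value = TRUE))) {
    expect_equal(w1[[nm]], w0[[nm]], info = nm)
  }
  expect_equal(diff(range(m$history$train_loss)), 0, tolerance = 1e-6)
})

test_that("the best checkpoint is restored and matches the history", {
  x <- separable_set(seed = 2)
  mon <- separable_set(seed = 3)
  m <- build_model(small_spec(), seed = 4)
  m <- train_model(m, x, monitor_set = mon,
                   config = train_config(epochs = 15, batch_size = 8,
                                         monitor_split = "eval", seed = 1))
  h <- m$history
  expect_equal(attr(h, "best_accuracy"), max(h$monitor_accuracy))
  expect_equal(attr(h, "best_epoch"),
               which.max(h$monitor_accuracy))  # earliest max on ties
  # re-evaluating the restored weights reproduces the best monitored value
  ev <- evaluate_model(m, mon)
  expect_equal(ev$report$accuracy, attr(h, "best_accuracy"))
})

test_that("an uninformative model scores at chance on balanced data", {
  x <- separable_set(n_per_class = 25)
  m <- build_model(small_spec(), seed = 6)
  w <- model_weights(m)
  w$dense[] <- 0
  w$dense_bias[] <- 0
  set_model_weights(m, w)
  p <- predict(m, x)
  expect_equal(unname(p), matrix(0.25, n_trials(x), 4), tolerance = 1e-6)
  # constant predictions leave three classes unpredicted: warns on their
  # empty precision denominators
  suppressWarnings(ev <- evaluate_model(m, x))
  # exactly uniform outputs: argmax ties break toward the lowest class
  expect_equal(ev$report$accuracy, 0.25)
  expect_equal(unique(ev$predictions$predicted), 0L)
})

test_that("shape and emptiness violations are rejected", {
  x <- separable_set()
  m <- build_model(small_spec(), seed = 1)
  bad <- tiny_epochs(n = 4, n_ch = 7, n_s = 160, n_cls = 4)
  expect_error(train_model(m, bad,
                           config = train_config(epochs = 1,
                                                 monitor_split = "train")),
               "channels")
  expect_error(evaluate_model(m, subset_epochs(x, integer(0))), "no trials")
  expect_error(train_model(m, x, config = train_config(monitor_split = "eval",
                                                       epochs = 1)),
               "monitor_set")
})

test_that("cross-entropy has its textbook fixed points", {
  expect_equal(cross_entropy(c(1, 0, 0, 0), 0), 0)
  expect_equal(cross_entropy(rep(0.25, 4), 2), log(4))
  expect_equal(cross_entropy(rep(0.25, 4), 2, base = 2), 2)  # bits
  p <- matrix(c(0.7, 0.1, 0.1, 0.1,
                0.25, 0.25, 0.25, 0.25), 2, byrow = TRUE)
  expect_equal(cross_entropy(p, c(0, 1)),
               mean(-log(c(0.7, 0.25))))
})

test_that("SGD optimizer updates weights too", {
  x <- separable_set()
  m <- build_model(small_spec(), seed = 2)
  w0 <- model_weights(m)
  m <- train_model(m, x, config = train_config(epochs = 2, batch_size = 8,
                                               optimizer = "sgd",
                                               learning_rate = 0.01,
                                               monitor_split = "train",
                                               seed = 1))
  expect_false(isTRUE(all.equal(model_weights(m)$dense, w0$dense)))
  expect_true(all(is.finite(m$history$train_loss)))
})
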